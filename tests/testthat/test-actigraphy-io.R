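test_that("epoch CSV round trip is bit-exact and epoch length is inferred", {
  set.seed(11)
  s <- epoch_series(rpois(2880 * 2, 40), "2024-03-04 00:00:00", 30, "rt",
                    light = runif(5760, 0, 500), off_wrist = rep(FALSE, 5760))
  path <- withr::local_tempfile(fileext = ".csv")
  write_epoch_csv(s, path)
  r <- read_epoch_csv(path, participant_id = "rt")
  expect_identical(r$activity, s$activity)
  expect_equal(r$epoch_length, 30)
  expect_equal(as.numeric(r$start), as.numeric(s$start))
  expect_equal(r$light, s$light)
})

test_that("epoch bookkeeping: 30-s epochs give 2880 bins per day, 17280 give 6 days", {
  one_day <- epoch_series(rep(1, 2880), "2024-03-04 00:00:00", 30)
  dm <- trim_to_full_days(one_day)
  expect_equal(dim(dm), c(1L, 2880L))
  six_days <- epoch_series(rep(1, 17280), "2024-03-04 00:00:00", 30)
  expect_equal(nrow(trim_to_full_days(six_days)), 6L)
})

test_that("a missing epoch row is reported as a gap at the right position", {
  df <- data.frame(
    timestamp = format(as.POSIXct("2024-03-04 00:00:00", tz = "UTC") +
                         c(0, 30, 60, 120, 150), "%Y-%m-%dT%H:%M:%S"),
    activity = c(5, 5, 5, 5, 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_epoch_csv(path), "rows 3 and 4")
})

test_that("negative counts and malformed inputs are rejected", {
  df <- data.frame(timestamp = format(as.POSIXct("2024-03-04", tz = "UTC") +
                                        c(0, 30), "%Y-%m-%dT%H:%M:%S"),
                   activity = c(5, -1))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_epoch_csv(path), "negative")
  expect_error(epoch_series(c(1, -2), "2024-03-04 00:00:00"), "non-negative")
  expect_error(epoch_series(c(1, NA), "2024-03-04 00:00:00"), "missing")
  expect_error(epoch_series(numeric(0), "2024-03-04 00:00:00"), "at least one")
  expect_error(epoch_series(1:10, "2024-03-04 00:00:00", epoch_length = 7),
               "divisor")
})

test_that("trimming discards partial days per brute-force window enumeration", {
  # starts 14:00, spans 6.5 days: enumerate complete midnight windows directly
  el <- 30
  n <- as.integer(6.5 * 86400 / el)
  s <- epoch_series(rep(1, n), "2024-03-04 14:00:00", el)
  t0 <- as.numeric(s$start)
  times <- t0 + (seq_len(n) - 1) * el
  midnights <- seq(as.numeric(as.POSIXct("2024-03-04 00:00:00", tz = "UTC")),
                   by = 86400, length.out = 10)
  complete <- sum(vapply(midnights, function(m) {
    m >= times[1] && (m + 86400 - el) <= times[n]
  }, logical(1)))
  expect_equal(nrow(trim_to_full_days(s)), complete)
  expect_equal(complete, 6L)

  # aligned input loses nothing
  s2 <- epoch_series(rep(2, 2 * 2880), "2024-03-04 00:00:00", 30)
  expect_equal(dim(trim_to_full_days(s2)), c(2L, 2880L))
  expect_error(trim_to_full_days(epoch_series(rep(1, 100), "2024-03-04 01:00:00")),
               "no complete day")
})

test_that("rebinning averages within bins and conserves the grand mean exactly", {
  set.seed(7)
  s <- epoch_series(rgamma(2880, 2, 0.01), "2024-03-04 00:00:00", 30)
  dm <- trim_to_full_days(s)
  hourly <- rebin_day_matrix(dm, 24)
  expect_equal(dim(hourly), c(1L, 24L))
  expect_equal(hourly[1, 1], mean(s$activity[1:120]))
  expect_equal(mean(hourly), mean(dm))
  expect_error(rebin_day_matrix(dm, 23), "divide")
})

test_that("day boundary is configurable and off-grid boundaries error", {
  s <- epoch_series(rep(1, 3 * 2880), "2024-03-04 06:00:00", 30)
  expect_equal(nrow(trim_to_full_days(s, day_start = "06:00")), 3L)
  expect_equal(nrow(trim_to_full_days(s, day_start = "00:00")), 2L)
  expect_error(trim_to_full_days(s, day_start = "00:00:07"), "epoch grid")
})

test_that("qc includes 5+ complete wear days and excludes short or night-only records", {
  full <- square_wave_series(days = 6)
  v <- qc_inclusion(full)
  expect_true(v$include)
  expect_length(v$reasons, 0)

  short <- square_wave_series(days = 4)
  v4 <- qc_inclusion(short)
  expect_false(v4$include)
  expect_true("insufficient_days" %in% v4$reasons)

  # watch worn 20:00-08:00 only: daytime is one long zero run every day
  night_only <- square_wave_series(days = 7, wake_h = 20, sleep_h = 8,
                                   active = 300, rest = 0)
  vn <- qc_inclusion(night_only)
  expect_false(vn$include)
  expect_true("night_only_wear" %in% vn$reasons)

  # DST overlap raises a flag, not an exclusion
  vd <- qc_inclusion(full, dst_dates = as.Date("2024-03-05"))
  expect_true(vd$include)
  expect_true("dst_transition_in_window" %in% vd$flags)
})

test_that("qc is monotone: appending complete wear days never flips include to exclude", {
  for (d in 5:8) {
    v_small <- qc_inclusion(square_wave_series(days = d))
    v_big <- qc_inclusion(square_wave_series(days = d + 2))
    expect_false(v_small$include && !v_big$include)
  }
})
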