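test_that("weighted-moving-average scorer matches a hand convolution", {
  # all-zero activity: every epoch sleeps
  expect_false(any(score_epochs(rep(0, 100))))
  # constant high activity: every epoch wakes
  expect_true(all(score_epochs(rep(1000, 100))))

  # single spike of 10,000 amid zeros: direct convolution oracle
  x <- rep(0, 41); x[21] <- 10000
  k <- actiware_kernel()
  oracle <- vapply(seq_along(x), function(i) {
    idx <- (i - 4):(i + 4)
    ok <- idx >= 1 & idx <= length(x)
    sum(k[ok] * x[idx[ok]]) > 40
  }, logical(1))
  expect_identical(score_epochs(x), oracle)
  expect_true(oracle[21])               # spike itself wakes
  expect_true(all(oracle[17:25]))       # whole kernel reach wakes (10000/25 > 40)
  expect_false(any(oracle[-(17:25)]))

  expect_error(score_epochs(rep(0, 5)), "longer than the series")
  expect_error(score_epochs(rep(0, 50), threshold = 0), "positive")
  expect_error(score_epochs(rep(0, 50), kernel = rep(1, 4)), "odd")
})

test_that("raising the wake threshold never decreases TST", {
  set.seed(42)
  sim <- generate_participant(reference_presets()$child_DS, seed = 9,
                              participant_id = "mono")
  iv <- resolve_rest_intervals(sim$series, sim$diary)
  tst <- vapply(c(20, 40, 80, 200), function(thr) {
    lab <- score_epochs(sim$series, threshold = thr)
    summarize_sleep(lab, iv, sim$series)$participant$tst_min
  }, numeric(1))
  expect_true(all(diff(tst) >= 0))
})

test_that("sleep summaries count minutes exactly and respect the onset rule", {
  s <- epoch_series(rep(0, 2880), "2024-03-04 00:00:00", 30, "n1")
  iv <- tibble::tibble(night = 1L,
                       start = as.POSIXct("2024-03-04 00:00:00", tz = "UTC"),
                       end = as.POSIXct("2024-03-04 08:00:00", tz = "UTC"))
  # perfect night
  sm <- summarize_sleep(rep(FALSE, 2880), iv, s)
  expect_equal(sm$per_night$tst_min, 480)
  expect_equal(sm$per_night$waso_min, 0)
  expect_equal(sm$per_night$se_pct, 100)

  # 60 scattered wake minutes after an onset at interval start
  lab <- rep(FALSE, 2880)
  wake_min <- seq(60, 296, by = 4)[1:60]       # minutes within the interval
  for (m in wake_min) lab[(2 * m + 1):(2 * m + 2)] <- TRUE
  sm2 <- summarize_sleep(lab, iv, s)
  expect_equal(sm2$per_night$tst_min, 420)
  expect_equal(sm2$per_night$waso_min, 60)
  expect_equal(sm2$per_night$se_pct, 87.5)

  # identity TST + WASO + pre-onset wake = duration, and onset rule skips
  # short early sleep runs
  lab3 <- rep(FALSE, 2880)
  lab3[1:18] <- TRUE                            # 9 min wake
  lab3[19:28] <- FALSE                          # 5 min sleep (below onset rule)
  lab3[29:40] <- TRUE                           # 6 min wake
  sm3 <- summarize_sleep(lab3, iv, s)
  expect_equal(sm3$per_night$pre_onset_wake_min, 15)
  expect_equal(sm3$per_night$tst_min + sm3$per_night$waso_min +
                 sm3$per_night$pre_onset_wake_min, 480)

  # all-wake interval is flagged and omitted
  sm4 <- summarize_sleep(rep(TRUE, 2880), iv, s)
  expect_true(sm4$per_night$flagged)
  expect_equal(sm4$participant$n_nights, 0)
})

test_that("the minute identity holds on simulated nights", {
  sim <- generate_participant(reference_presets()$adolescent_DS, seed = 4,
                              participant_id = "id")
  lab <- score_epochs(sim$series)
  iv <- resolve_rest_intervals(sim$series, sim$diary)
  sm <- summarize_sleep(lab, iv, sim$series)
  ok <- !sm$per_night$flagged
  expect_true(all(abs(sm$per_night$tst_min[ok] + sm$per_night$waso_min[ok] +
                        sm$per_night$pre_onset_wake_min[ok] -
                        sm$per_night$duration_min[ok]) < 1e-9))
})

test_that("diary rest intervals pass through exactly and wrap past midnight", {
  s <- square_wave_series(days = 3)
  d <- diary_record("sq", as.Date("2024-03-04") + 0:1,
                    bedtime = c("21:00", "22:30"),
                    waketime = c("06:30", "08:00"))
  iv <- resolve_rest_intervals(s, d)
  expect_equal(as.numeric(iv$end - iv$start, units = "hours"), c(9.5, 9.5))
  expect_equal(format(iv$start[1], "%H:%M"), "21:00")
  expect_true(all(iv$source == "diary"))
})

test_that("diary-free rest intervals land within a bin of the square-wave truth", {
  s <- square_wave_series(days = 6, wake_h = 7, sleep_h = 22, active = 500)
  iv <- resolve_rest_intervals(s, diary = NULL)
  expect_gte(nrow(iv), 4)
  starts <- as.numeric(iv$start) %% 86400 / 3600
  ends <- as.numeric(iv$end) %% 86400 / 3600
  expect_true(all(abs(starts - 22) <= 0.11))
  expect_true(all(abs(ends - 7) <= 0.11))
})

test_that("estimated WASO tracks the simulated arousal-minute ground truth", {
  errs <- vapply(1:6, function(seed) {
    sim <- generate_participant(reference_presets()$child_DS, seed = 100 + seed,
                                participant_id = "w")
    lab <- score_epochs(sim$series)
    iv <- resolve_rest_intervals(sim$series, sim$diary)
    sm <- summarize_sleep(lab, iv, sim$series)
    sm$participant$waso_min - mean(sim$truth$arousal_min)
  }, numeric(1))
  # scorer-detected WASO = true bout minutes + kernel smear at bout edges;
  # the offset is bounded and positive on average
  expect_true(mean(errs) > 0)
  expect_true(all(abs(errs) < 30))
})
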