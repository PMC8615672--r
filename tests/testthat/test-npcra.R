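test_that("interdaily stability hits its boundary cases", {
  # identical daily profile repeated: IS = 1 exactly
  set.seed(2)
  prof <- rgamma(24, 2, 0.01)
  dm <- tiled_day_matrix(prof, days = 6)
  expect_equal(interdaily_stability(dm), 1.0, tolerance = 1e-12)

  # 2-day, 4-bin anti-phase toy matrix: direct formula evaluation oracle
  m <- rbind(c(0, 0, 10, 10), c(10, 10, 0, 0))
  x <- as.numeric(m); p <- ncol(m); n <- length(x)
  oracle <- (n * sum((colMeans(m) - mean(x))^2)) / (p * sum((x - mean(x))^2))
  expect_equal(interdaily_stability(m), oracle)
  expect_equal(oracle, 0)              # perfectly anti-phase days

  # exchangeable noise: E[IS] ~ 1/D
  set.seed(99)
  vals <- replicate(150, interdaily_stability(matrix(rnorm(144), 6, 24)))
  expect_equal(mean(vals), 1 / 6, tolerance = 0.02)

  expect_warning(is0 <- interdaily_stability(matrix(3, 4, 24)), "zero-variance")
  expect_true(is.na(is0))
})

test_that("intradaily variability matches direct formula evaluation", {
  iv_oracle <- function(x) {
    n <- length(x)
    (n * sum(diff(x)^2)) / ((n - 1) * sum((x - mean(x))^2))
  }
  # slowly varying sinusoid: IV well below 1
  t_h <- 1:144
  slow <- 100 + 50 * sin(2 * pi * t_h / 24)
  expect_equal(intradaily_variability(slow), iv_oracle(slow))
  expect_lt(intradaily_variability(slow), 0.2)

  # strict hourly alternation: near the anticorrelated maximum
  alt <- rep(c(0, 100), 72)
  expect_equal(intradaily_variability(alt), iv_oracle(alt))
  expect_gt(intradaily_variability(alt), 3.9)

  # matrix input flattens day by day
  m <- matrix(rgamma(72, 2), 3, 24)
  expect_equal(intradaily_variability(m), iv_oracle(as.numeric(t(m))))

  expect_warning(iv0 <- intradaily_variability(rep(2, 48)), "zero-variance")
  expect_true(is.na(iv0))
})

test_that("IS and IV are invariant under affine transforms", {
  set.seed(12)
  m <- matrix(rgamma(144, 1.5, 0.01), 6, 24)
  for (ab in list(c(2.5, 0), c(1, 40), c(-3, 500), c(0.1, 7))) {
    m2 <- ab[1] * m + ab[2]
    expect_equal(interdaily_stability(m2), interdaily_stability(m),
                 tolerance = 1e-10)
    expect_equal(intradaily_variability(m2), intradaily_variability(m),
                 tolerance = 1e-10)
  }
})

test_that("L5/M10 equal brute-force enumeration over all 24 wrap-around windows", {
  brute <- function(profile, len) {
    means <- vapply(0:23, function(s)
      mean(profile[((s + 0:(len - 1)) %% 24) + 1]), numeric(1))
    means
  }
  set.seed(8)
  for (rep in 1:25) {
    prof <- rgamma(24, 0.8, 0.01)
    r <- l5_m10(prof)
    b5 <- brute(prof, 5); b10 <- brute(prof, 10)
    expect_equal(r$l5, min(b5))
    expect_equal(r$m10, max(b10))
    expect_equal(r$l5_onset_hours, which.min(b5) - 1)   # earliest tie wins
    expect_equal(r$m10_onset_hours, which.max(b10) - 1)
  }

  # square-wave profile: windows nest inside the constant stretches
  prof <- ifelse(1:24 %in% c(22:24, 1:7), 0, 600)
  r <- l5_m10(prof)
  expect_equal(r$l5, 0)
  expect_equal(r$m10, 600)

  # single active hour spreads over the 10-h window mean
  prof1 <- rep(0, 24); prof1[13] <- 240
  expect_equal(l5_m10(prof1)$m10, 24)
})

test_that("relative amplitude follows its definition and degenerate rules", {
  expect_equal(relative_amplitude(0, 500), 1)
  expect_equal(relative_amplitude(250, 250), 0)
  expect_equal(relative_amplitude(13.76, 687.0), (687 - 13.76) / (687 + 13.76))
  expect_equal(round(relative_amplitude(13.76, 687.0), 4), 0.9607)
  expect_warning(ra0 <- relative_amplitude(0, 0), "undefined")
  expect_true(is.na(ra0))
})

test_that("IS falls with day-to-day phase jitter; IV rises with arousal rate", {
  p0 <- reference_presets()$child_DS
  mean_metric <- function(p, field, n = 12, seed0 = 500) {
    mean(vapply(seq_len(n), function(j) {
      sim <- generate_participant(p, seed = seed0 + j, participant_id = "m")
      dm <- trim_to_full_days(sim$series, bins_per_day = 24)
      if (field == "is") interdaily_stability(dm) else intradaily_variability(dm)
    }, numeric(1)))
  }
  is_by_jitter <- vapply(c(0.1, 0.8, 1.8), function(j) {
    p <- p0; p$offset_sd_night <- j
    mean_metric(p, "is")
  }, numeric(1))
  expect_true(all(diff(is_by_jitter) < 0))

  iv_by_rate <- vapply(c(0, 12, 40), function(r) {
    p <- p0; p$arousal_rate <- r
    mean_metric(p, "iv")
  }, numeric(1))
  expect_true(all(diff(iv_by_rate) > 0))
})
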