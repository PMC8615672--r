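test_that("generation is bit-identical for identical (params, seed)", {
  p <- reference_presets()$adolescent_TD
  a <- generate_participant(p, seed = 5, participant_id = "a")
  b <- generate_participant(p, seed = 5, participant_id = "a")
  expect_identical(a$series$activity, b$series$activity)
  expect_identical(a$truth, b$truth)
  c <- generate_participant(p, seed = 6, participant_id = "a")
  expect_false(identical(a$series$activity, c$series$activity))
})

test_that("a perfectly regular sleeper yields IS = 1 exactly and WASO = 0", {
  sim <- generate_participant(deterministic_params(), seed = 1,
                              participant_id = "det",
                              start_date = "2024-03-04")
  dm <- trim_to_full_days(sim$series, bins_per_day = 24)
  expect_equal(interdaily_stability(dm), 1.0, tolerance = 1e-12)
  lab <- score_epochs(sim$series)
  iv <- resolve_rest_intervals(sim$series, sim$diary)
  sm <- summarize_sleep(lab, iv, sim$series)
  expect_equal(sm$participant$waso_min, 0)
  expect_equal(sum(sim$truth$arousal_min), 0)
})

test_that("doubling the arousal rate raises mean detected WASO", {
  p <- reference_presets()$child_TD
  waso_at <- function(rate, n = 20) {
    p$arousal_rate <- rate
    mean(vapply(seq_len(n), function(j) {
      sim <- generate_participant(p, seed = 600 + j, participant_id = "w")
      sm <- summarize_sleep(score_epochs(sim$series),
                            resolve_rest_intervals(sim$series, sim$diary),
                            sim$series)
      sm$participant$waso_min
    }, numeric(1)))
  }
  expect_gt(waso_at(p$arousal_rate * 2), waso_at(p$arousal_rate))
})

test_that("the children-DS preset reproduces the reference TST within 2 SE", {
  p <- reference_presets()$child_DS
  tst <- vapply(seq_len(p$n), function(j) {
    sim <- generate_participant(p, seed = 4000 + j, participant_id = "t")
    sm <- summarize_sleep(score_epochs(sim$series),
                          resolve_rest_intervals(sim$series, sim$diary),
                          sim$series)
    sm$participant$tst_min
  }, numeric(1))
  ref <- reference_cohort_summary()
  r <- ref[ref$group == "DS" & ref$age_group == "child", ]
  expect_lt(abs(mean(tst) - r$tst_min_mean),
            2 * r$tst_min_sd / sqrt(p$n))
})

test_that("cohort generation links cognition to interdaily stability with planted signs", {
  presets <- reference_presets()
  presets <- presets[c("child_DS", "adolescent_DS")]
  presets$child_DS$n <- 12; presets$adolescent_DS$n <- 12
  ch <- generate_cohort(presets, seed = 17)
  expect_equal(nrow(ch$info), 24)
  expect_true(all(c("reaction_time", "verbal_recall", "scene_recall",
                    "kbit_verbal", "weekend_days", "is_true") %in%
                    names(ch$info)))
  expect_true(all(ch$info$is_true > 0 & ch$info$is_true <= 1))
  expect_true(all(ch$info$age >= 6 & ch$info$age <= 18))

  # same master seed regenerates the same cohort
  ch2 <- generate_cohort(presets, seed = 17)
  expect_identical(ch$info, ch2$info)

  # planted positive reaction-time slope on IS is recoverable at n ~ 39
  hits <- vapply(1:10, function(seed) {
    presets39 <- reference_presets()[c("child_DS", "adolescent_DS", "adult_DS")]
    presets39$child_DS$n <- 13; presets39$adolescent_DS$n <- 13
    presets39$adult_DS$n <- 13
    cc <- generate_cohort(presets39, seed = 800 + seed)
    d <- cc$info
    d$is <- d$is_true; d$se_pct <- stats::rnorm(nrow(d), 86, 4)
    f <- fit_hierarchical_model(d, "reaction_time")
    co <- f$coefficients
    co$estimate[co$term == "is"] > 0 & co$p_raw[co$term == "is"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.6)
})

test_that("null cognitive linkage produces no corrected IS discoveries", {
  presets <- reference_presets()[c("child_DS", "adolescent_DS", "adult_DS")]
  presets <- lapply(presets, function(p) { p$n <- 16; p })
  betas <- default_cognitive_betas()
  betas$b_is <- 0; betas$b_age <- 0
  cc <- generate_cohort(presets, betas = betas, seed = 23)
  d <- cc$info
  d$is <- d$is_true; d$se_pct <- stats::rnorm(nrow(d), 85, 4)
  pvals <- vapply(c("reaction_time", "verbal_recall", "scene_recall",
                    "visual_recall", "spatial_recall"), function(oc) {
    tr <- c(reaction_time = "none", verbal_recall = "log", scene_recall = "log",
            visual_recall = "sqrt", spatial_recall = "none")[[oc]]
    f <- fit_hierarchical_model(d, oc, transform = tr)
    f$coefficients$p_raw[f$coefficients$term == "is"]
  }, numeric(1))
  expect_true(all(holm_correct(pvals) > 0.05))
})

test_that("cohort CSVs round-trip through the io module", {
  presets <- list(mini = reference_presets()$child_TD)
  presets$mini$n <- 2
  dir <- withr::local_tempdir()
  ch <- generate_cohort(presets, seed = 3, out_dir = dir)
  expect_true(file.exists(file.path(dir, "diary.csv")))
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  back <- read_cohort_csvs(dir)
  pid <- names(ch$participants)[1]
  expect_equal(back$participants[[pid]]$series$activity,
               ch$participants[[pid]]$series$activity)
  expect_equal(nrow(back$info), 2)
})
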