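test_that("residual normality gate separates Gaussian from heavy-tailed outcomes", {
  picks <- vapply(1:20, function(seed) {
    d <- toy_cohort(n_per_cell = 10, seed = seed)
    residual_normality_gate(d, "y", c("group", "age_group"))$method
  }, character(1))
  expect_gte(mean(picks == "permutation"), 0.9)

  picks_t1 <- vapply(1:20, function(seed) {
    d <- toy_cohort(n_per_cell = 10, seed = seed)
    set.seed(seed + 1000)
    d$y <- rt(nrow(d), df = 1)
    residual_normality_gate(d, "y", c("group", "age_group"))$method
  }, character(1))
  expect_gte(mean(picks_t1 == "kruskal_wallis"), 0.9)

  d <- toy_cohort(); d$y <- 1
  expect_error(residual_normality_gate(d, "y", c("group", "age_group")),
               "constant")
})

test_that("permutation ANOVA returns p = 1 for a flat outcome and is seeded deterministically", {
  d <- toy_cohort(n_per_cell = 6)
  d$y <- 5
  res <- permutation_anova(d, "y", c("group", "age_group"), n_perm = 999, seed = 3)
  expect_equal(res$p_raw, rep(1, 3))

  d2 <- toy_cohort(n_per_cell = 8, effect = 0.8, seed = 2)
  a <- permutation_anova(d2, "y", c("group", "age_group"), n_perm = 999, seed = 11)
  b <- permutation_anova(d2, "y", c("group", "age_group"), n_perm = 999, seed = 11)
  expect_identical(a$p_raw, b$p_raw)
  expect_true(all(c("group", "age_group", "group:age_group") %in% a$term))
})

test_that("a large single-factor effect is detected at the permutation floor", {
  set.seed(14)
  d <- data.frame(group = rep(c("a", "b"), each = 20),
                  y = c(rnorm(20, 0), rnorm(20, 5)))
  res <- permutation_anova(d, "y", "group", n_perm = 9999, seed = 5)
  expect_lte(res$p_raw, 0.001)
})

test_that("permutation p-values converge across seeds at 9999 permutations", {
  d <- toy_cohort(n_per_cell = 7, effect = 0.9, seed = 8)
  p1 <- permutation_anova(d, "y", c("group", "age_group"), 9999, seed = 1)$p_raw
  p2 <- permutation_anova(d, "y", c("group", "age_group"), 9999, seed = 2)$p_raw
  expect_true(all(abs(p1 - p2) <= 0.01))
})

test_that("Kruskal-Wallis matches an independent tie-corrected rank oracle", {
  kw_oracle <- function(y, g) {
    r <- rank(y); N <- length(y)
    h <- 12 / (N * (N + 1)) *
      sum(tapply(r, g, function(ri) sum(ri)^2 / length(ri))) - 3 * (N + 1)
    ties <- table(y)
    h / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  # small shifted-uniform groups
  set.seed(4)
  d <- data.frame(f = rep(c("a", "b", "c"), times = c(3, 3, 2)))
  d$y <- runif(8) + c(0, 0.3, 0.8)[as.integer(factor(d$f))]
  res <- kruskal_wallis_per_factor(d, "y", "f")
  expect_equal(res$statistic, kw_oracle(d$y, d$f), tolerance = 1e-10)
  expect_equal(res$df, 2)

  # tie-heavy data exercises the correction term
  d2 <- data.frame(f = rep(c("a", "b", "c"), each = 5),
                   y = c(1, 1, 2, 2, 3, 1, 2, 2, 3, 3, 2, 3, 3, 3, 1))
  res2 <- kruskal_wallis_per_factor(d2, "y", "f")
  expect_equal(res2$statistic, kw_oracle(d2$y, d2$f), tolerance = 1e-10)

  # identical ranks across levels
  d3 <- data.frame(f = rep(c("a", "b"), each = 3), y = rep(c(1, 2, 3), 2))
  expect_equal(kruskal_wallis_per_factor(d3, "y", "f")$statistic, 0)
  expect_equal(kruskal_wallis_per_factor(d3, "y", "f")$p_raw, 1)
})

test_that("Holm correction reproduces the hand computation and its invariances", {
  expect_equal(holm_correct(0.04), 0.04)
  expect_equal(holm_correct(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  set.seed(6)
  p <- runif(9)
  expect_true(all(holm_correct(p) >= p))
  ord <- sample(9)
  expect_equal(holm_correct(p[ord]), holm_correct(p)[ord])
  expect_true(all(holm_correct(p) <= 1))
})

test_that("the gated protocol assembles per-term Holm families across outcomes", {
  set.seed(10)
  d <- toy_cohort(n_per_cell = 8, effect = 1.2)
  d$y2 <- rnorm(nrow(d))
  res <- anova_protocol(d, c("y", "y2"), c("group", "age_group"),
                        n_perm = 999, seed = 2)
  expect_true(all(res$p_corrected >= res$p_raw))
  # per-term family: two outcomes' group tests corrected together
  grp <- res[res$term == "group", ]
  expect_equal(grp$p_corrected, holm_correct(grp$p_raw))
})

test_that("hierarchical models apply transform, outlier exclusion and interaction trimming", {
  set.seed(20)
  n <- 40
  d <- data.frame(participant_id = sprintf("p%02d", 1:n),
                  is = runif(n, 0.5, 0.9), se_pct = rnorm(n, 86, 4),
                  age = runif(n, 6, 26), gender = sample(c("F", "M"), n, TRUE),
                  weekend_days = sample(1:2, n, TRUE))
  d$rt <- 0.8 + 2.5 * d$is + 0.05 * d$age + rnorm(n, 0, 0.3)

  fit <- fit_hierarchical_model(d, "rt")
  expect_equal(fit$n, n)
  expect_gt(fit$coefficients$estimate[fit$coefficients$term == "is"], 0)
  expect_lt(fit$coefficients$p_raw[fit$coefficients$term == "is"], 0.05)
  expect_gt(fit$r_squared, 0.3)

  # planted outlier at > 5 SD is excluded and logged
  d2 <- d
  d2$rt[7] <- d$rt[7] + 8 * sd(d$rt)
  fit2 <- fit_hierarchical_model(d2, "rt")
  expect_equal(fit2$n, n - 1)
  expect_equal(fit2$excluded_ids, "p07")

  # log transform linearizes a multiplicative outcome
  d$vr <- exp(3.2 - 2 * d$is + rnorm(n, 0, 0.25))
  fit3 <- fit_hierarchical_model(d, "vr", transform = "log")
  expect_equal(fit3$transform, "log")
  expect_lt(fit3$coefficients$estimate[fit3$coefficients$term == "is"], 0)

  # strong planted interaction is retained; a null interaction is trimmed in
  # most replicates (the 0.10 retention threshold admits ~10-15% false keeps)
  d$yi <- 1 + 0.2 * d$is + 0.02 * d$age + 2.5 * d$is * (d$age - 16) + rnorm(n, 0, 0.3)
  fit4 <- fit_hierarchical_model(d, "yi")
  expect_true(fit4$interaction_retained)
  kept_null <- vapply(1:20, function(seed) {
    set.seed(700 + seed)
    d$y0 <- 0.8 + 2.5 * d$is + 0.05 * d$age + rnorm(n, 0, 0.3)
    fit_hierarchical_model(d, "y0")$interaction_retained
  }, logical(1))
  expect_lte(mean(kept_null), 0.4)

  # null outcome rarely yields a significant focal coefficient
  hits <- vapply(1:20, function(seed) {
    set.seed(300 + seed)
    d$null_y <- rnorm(n)
    f <- fit_hierarchical_model(d, "null_y")
    f$coefficients$p_raw[f$coefficients$term == "is"] < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.2)
})
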