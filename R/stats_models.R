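# Inferential protocol: residual-normality gating, Freedman-Lane permutation
# ANOVA with Type-II sums of squares, per-factor Kruskal-Wallis fallback,
# Holm correction, and the hierarchical linear models for cognitive outcomes.

#' Choose permutation ANOVA vs Kruskal-Wallis by residual normality
#'
#' Fits the two-factor cell-means model and applies a Shapiro-Wilk test to its
#' residuals: normal residuals (p >= alpha) select the permutation ANOVA,
#' non-normal residuals select per-factor Kruskal-Wallis tests.
#'
#' @param data data frame with the outcome and factor columns.
#' @param outcome outcome column name.
#' @param factors character vector of one or two factor column names.
#' @param alpha Shapiro-Wilk significance level (default 0.05).
#' @return list: `method` (`"permutation"` or `"kruskal_wallis"`),
#'   `shapiro_p`.
#' @export
residual_normality_gate <- function(data, outcome, factors, alpha = 0.05) {
  df <- stats::na.omit(data[, c(outcome, factors)])
  if (nrow(df) < 3L) stop("fewer than 3 complete observations", call. = FALSE)
  y <- df[[outcome]]
  if (stats::var(y) == 0) stop("outcome is constant: residuals degenerate", call. = FALSE)
  cells <- interaction(df[factors], drop = TRUE)
  res <- y - stats::ave(y, cells)
  if (stats::var(res) == 0) stop("cell-means residuals are constant", call. = FALSE)
  p <- stats::shapiro.test(res)$p.value
  list(method = if (p < alpha) "kruskal_wallis" else "permutation",
       shapiro_p = p)
}

# Residual sum of squares of y (vector or matrix of columns) under design X.
rss_under <- function(qr_x, y) {
  r <- qr.resid(qr_x, y)
  if (is.matrix(r)) colSums(r^2) else sum(r^2)
}

#' Two-factor permutation ANOVA (Freedman-Lane, Type-II)
#'
#' Observed F statistics come from the Type-II sums-of-squares decomposition
#' of the two-way (or one-way) fixed-effects ANOVA; the null distribution of
#' each term's F is built by Freedman-Lane permutation of the reduced-model
#' residuals, which handles unbalanced designs. The p-value is
#' `(1 + #(F* >= F)) / (1 + n_perm)` and is reproducible bit-exactly for a
#' fixed seed.
#'
#' @param data data frame.
#' @param outcome outcome column name.
#' @param factors one or two factor column names (e.g. group and age group).
#' @param n_perm number of permutations (>= 999; default 9999).
#' @param seed RNG seed.
#' @return tibble of class `anova_result`: one row per term (`factors` plus
#'   their interaction when both are present) with `df`, `statistic`,
#'   `p_raw`, `method`, `n_perm`, `seed`.
#' @export
permutation_anova <- function(data, outcome, factors, n_perm = 9999,
                              seed = 1L) {
  if (n_perm < 999) stop("n_perm must be at least 999", call. = FALSE)
  df <- stats::na.omit(data[, c(outcome, factors)])
  for (f in factors) df[[f]] <- droplevels(factor(df[[f]]))
  keep <- vapply(factors, function(f) nlevels(df[[f]]) >= 2L, logical(1))
  if (!all(keep)) {
    warning("dropping single-level factor(s): ",
            paste(factors[!keep], collapse = ", "))
    factors <- factors[keep]
  }
  if (length(factors) == 0L) stop("no testable factor remains", call. = FALSE)
  y <- df[[outcome]]
  n <- length(y)

  mm <- function(fml) qr(stats::model.matrix(fml, data = df))
  if (length(factors) == 2L) {
    a <- factors[1]; b <- factors[2]
    q_a <- mm(stats::reformulate(a))
    q_b <- mm(stats::reformulate(b))
    q_ab <- mm(stats::reformulate(c(a, b)))
    q_full <- mm(stats::reformulate(paste(a, b, sep = "*")))
    terms <- list(
      # term = c(label, reduced qr, nested qr); Type II: main effects tested
      # ignoring the interaction, interaction tested against both mains.
      list(label = a, red = q_b, big = q_ab,
           df = nlevels(df[[a]]) - 1L),
      list(label = b, red = q_a, big = q_ab,
           df = nlevels(df[[b]]) - 1L),
      list(label = paste0(a, ":", b), red = q_ab, big = q_full,
           df = (nlevels(df[[a]]) - 1L) * (nlevels(df[[b]]) - 1L))
    )
    q_err <- q_full
  } else {
    a <- factors[1]
    q_0 <- qr(matrix(1, n, 1))
    q_a <- mm(stats::reformulate(a))
    terms <- list(list(label = a, red = q_0, big = q_a,
                       df = nlevels(df[[a]]) - 1L))
    q_err <- q_a
  }
  df_err <- n - q_err$rank
  if (df_err <= 0) stop("no residual degrees of freedom", call. = FALSE)

  f_stat <- function(yy, term) {
    ss <- rss_under(term$red, yy) - rss_under(term$big, yy)
    mse <- rss_under(q_err, yy) / df_err
    f <- (ss / term$df) / mse
    # a flat outcome has no effect: F = 0, not 0/0
    f[mse <= .Machine$double.eps & ss <= 1e-12] <- 0
    f
  }

  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))
  rows <- lapply(terms, function(tm) {
    f_obs <- f_stat(y, tm)
    fit_red <- qr.fitted(tm$red, y)
    res_red <- y - fit_red
    y_star <- fit_red + matrix(res_red[perms], nrow = n)
    f_null <- f_stat(y_star, tm)
    tibble::tibble(term = tm$label, df = tm$df, statistic = f_obs,
                   p_raw = (1 + sum(f_null >= f_obs)) / (1 + n_perm),
                   method = "permutation", n_perm = n_perm, seed = seed)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("anova_result", class(out))
  out
}

#' Kruskal-Wallis rank test per factor
#'
#' Tie-corrected Kruskal-Wallis chi-squared statistic for a single factor,
#' the fallback for outcomes with non-normal residuals (no interaction term
#' is testable under this method).
#'
#' @param data data frame.
#' @param outcome outcome column name.
#' @param factor_name single factor column name.
#' @return tibble of class `anova_result` with `term`, `df`, `statistic`
#'   (chi-squared), `p_raw`, `method = "kruskal_wallis"`.
#' @export
kruskal_wallis_per_factor <- function(data, outcome, factor_name) {
  df <- stats::na.omit(data[, c(outcome, factor_name)])
  g <- droplevels(factor(df[[factor_name]]))
  kt <- stats::kruskal.test(df[[outcome]], g)
  out <- tibble::tibble(term = factor_name,
                        df = unname(kt$parameter),
                        statistic = unname(kt$statistic),
                        p_raw = kt$p.value,
                        method = "kruskal_wallis",
                        n_perm = NA_integer_, seed = NA_integer_)
  class(out) <- c("anova_result", class(out))
  out
}

#' Holm step-down correction
#'
#' Step-down Holm adjustment with monotonicity enforcement; invariant to the
#' input order and idempotent on already-corrected families. Family membership
#' is whatever vector the caller assembles (the default protocol groups all
#' outcomes' tests of the same factor into one family).
#'
#' @param pvals numeric vector of raw p-values in `[0, 1]`.
#' @return corrected p-values, elementwise >= the raw ones, in input order.
#' @export
holm_correct <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "holm")
}

#' Gated ANOVA protocol over a family of outcomes
#'
#' For each outcome: choose the method by [residual_normality_gate()], run the
#' two-factor Freedman-Lane permutation ANOVA or per-factor Kruskal-Wallis
#' tests, then Holm-correct within per-term families across outcomes (all
#' "group" tests form one family, all "age" tests another, and so on).
#'
#' @param data cohort table.
#' @param outcomes character vector of outcome column names.
#' @param factors two factor column names.
#' @param n_perm,seed passed to [permutation_anova()].
#' @param holm_family `"per_term"` (default) or `"per_outcome"`.
#' @return tibble: `outcome`, `term`, `df`, `statistic`, `p_raw`,
#'   `p_corrected`, `method`.
#' @export
anova_protocol <- function(data, outcomes, factors, n_perm = 9999, seed = 1L,
                           holm_family = c("per_term", "per_outcome")) {
  holm_family <- match.arg(holm_family)
  rows <- lapply(outcomes, function(oc) {
    gate <- residual_normality_gate(data, oc, factors)
    res <- if (gate$method == "permutation") {
      permutation_anova(data, oc, factors, n_perm = n_perm, seed = seed)
    } else {
      dplyr::bind_rows(lapply(factors, function(f)
        kruskal_wallis_per_factor(data, oc, f)))
    }
    res$outcome <- oc
    res$shapiro_p <- gate$shapiro_p
    res
  })
  out <- dplyr::bind_rows(rows)
  fam <- if (holm_family == "per_term") out$term else out$outcome
  out$p_corrected <- stats::ave(out$p_raw, fam,
                                FUN = function(p) holm_correct(p))
  out[, c("outcome", "term", "df", "statistic", "p_raw", "p_corrected",
          "method", "shapiro_p")]
}

#' Hierarchical linear model for a cognitive outcome
#'
#' The study-style forward protocol: (1) transform the outcome (`log`,
#' `sqrt` or none); (2) exclude outcome values more than `outlier_sd`
#' standard deviations from the mean (on the transformed scale); (3) fit the
#' main-effects model `outcome ~ predictor + covariates` by least squares on
#' complete cases; (4) add the `predictor x moderator` interaction (age,
#' measured continuously, by default); (5) retain the interaction only if its
#' p-value is at most `interaction_alpha` or it significantly improves the
#' model R-squared (nested-model F test at `r2_alpha`).
#'
#' @param data data frame.
#' @param outcome outcome column name.
#' @param predictor focal predictor (default `"is"`, interdaily stability).
#' @param covariates covariate column names (default sleep efficiency, age,
#'   gender, full weekend days of recording).
#' @param moderator interaction partner of the predictor (default `"age"`).
#' @param transform `"none"`, `"log"` or `"sqrt"`.
#' @param extra_covariates additional covariates (e.g. a task-accuracy
#'   covariate for reaction-time models).
#' @param outlier_sd outlier exclusion threshold in SDs (default 3).
#' @param interaction_alpha retention threshold for the interaction p-value.
#' @param r2_alpha alpha of the nested-model F test for the R-squared
#'   contribution criterion.
#' @return list of class `model_result`: `coefficients` tibble (`term`,
#'   `estimate`, `se`, `p_raw`), `r_squared`, `n`, `excluded_ids`,
#'   `interaction_retained`, `transform`, `fit` (the final `lm`).
#' @export
fit_hierarchical_model <- function(data, outcome, predictor = "is",
                                   covariates = c("se_pct", "age", "gender",
                                                  "weekend_days"),
                                   moderator = "age",
                                   transform = c("none", "log", "sqrt"),
                                   extra_covariates = NULL,
                                   outlier_sd = 3, interaction_alpha = 0.10,
                                   r2_alpha = 0.05) {
  transform <- match.arg(transform)
  vars <- c(outcome, predictor, covariates, extra_covariates)
  id_col <- intersect(c("participant_id", "id"), names(data))[1]
  df <- data[stats::complete.cases(data[, vars]), , drop = FALSE]
  if (nrow(df) < 10L) stop("fewer than 10 complete rows for ", outcome, call. = FALSE)
  y <- df[[outcome]]
  y <- switch(transform,
              none = y,
              log = {
                if (any(y <= 0)) stop("log transform needs positive outcomes", call. = FALSE)
                log(y)
              },
              sqrt = {
                if (any(y < 0)) stop("sqrt transform needs non-negative outcomes", call. = FALSE)
                sqrt(y)
              })
  z <- (y - mean(y)) / stats::sd(y)
  out_idx <- which(abs(z) > outlier_sd)
  excluded <- if (!is.na(id_col)) as.character(df[[id_col]][out_idx]) else as.character(out_idx)
  if (length(out_idx)) {
    df <- df[-out_idx, , drop = FALSE]
    y <- y[-out_idx]
  }
  df$.y <- y
  rhs <- c(predictor, covariates, extra_covariates)
  fml_main <- stats::reformulate(rhs, response = ".y")
  fit_main <- stats::lm(fml_main, data = df)
  alias <- alias(fit_main)$Complete
  if (!is.null(alias))
    stop("rank-deficient design; collinear terms: ",
         paste(rownames(alias), collapse = ", "), call. = FALSE)
  inter <- paste0(predictor, ":", moderator)
  fml_full <- stats::update(fml_main, paste(". ~ . +", inter))
  fit_full <- stats::lm(fml_full, data = df)
  cf_full <- summary(fit_full)$coefficients
  inter_row <- grep(":", rownames(cf_full))
  p_inter <- if (length(inter_row)) cf_full[inter_row[1], 4] else NA_real_
  f_cmp <- stats::anova(fit_main, fit_full)
  p_nested <- f_cmp[["Pr(>F)"]][2]
  keep_inter <- isTRUE(p_inter <= interaction_alpha) ||
    isTRUE(p_nested <= r2_alpha)
  fit <- if (keep_inter) fit_full else fit_main
  sm <- summary(fit)
  coefs <- tibble::tibble(term = rownames(sm$coefficients),
                          estimate = sm$coefficients[, 1],
                          se = sm$coefficients[, 2],
                          p_raw = sm$coefficients[, 4])
  structure(list(outcome = outcome, transform = transform,
                 coefficients = coefs,
                 r_squared = sm$r.squared,
                 n = nrow(df), excluded_ids = excluded,
                 interaction_retained = keep_inter,
                 interaction_p = p_inter,
                 fit = fit),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s (%s transform): n = %d, R^2 = %.3f, interaction %s\n",
              x$outcome, x$transform, x$n, x$r_squared,
              if (x$interaction_retained) "retained" else "trimmed"))
  print(x$coefficients)
  invisible(x)
}
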