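# Non-parametric circadian rhythm analysis (van Someren formulation):
# interdaily stability, intradaily variability, L5/M10 and relative amplitude.
# All are computed on hourly-binned data by default, the classical convention.

#' Interdaily stability (IS)
#'
#' Ratio of the variance of the average 24-h profile to the total variance:
#' `IS = (N * sum_h (xbar_h - xbar)^2) / (p * sum_i (x_i - xbar)^2)` with `p`
#' bins per day and `N = D * p` observations. IS is 1 for a daily profile
#' repeated identically across days and tends to `1/D` for exchangeable noise.
#'
#' @param dm a [day_matrix] (hourly bins by convention) with at least 2 days,
#'   or a plain `D x p` matrix.
#' @return IS in `[0, 1]`; `NA` with a warning for a zero-variance series.
#' @export
interdaily_stability <- function(dm) {
  m <- unclass(dm)
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  x <- as.numeric(m)
  denom <- sum((x - mean(x))^2)
  if (denom == 0) {
    warning("zero-variance series: interdaily stability undefined")
    return(NA_real_)
  }
  p <- ncol(m)
  n <- length(x)
  hourly_means <- colMeans(m)
  (n * sum((hourly_means - mean(x))^2)) / (p * denom)
}

#' Intradaily variability (IV)
#'
#' Normalized mean-square successive difference of the hourly series:
#' `IV = (N * sum_{i=2}^{N} (x_i - x_{i-1})^2) / ((N-1) * sum_i (x_i - xbar)^2)`.
#' Values near 0 indicate few rest-activity transitions; independent noise
#' gives values near 2 (slightly above 2 is possible for anticorrelated
#' series). Computed over the concatenated retained days without resetting at
#' day boundaries.
#'
#' @param x hourly activity sequence (numeric vector or a [day_matrix], which
#'   is flattened day by day).
#' @return IV; `NA` with a warning for a zero-variance series.
#' @export
intradaily_variability <- function(x) {
  if (is.matrix(x)) x <- as.numeric(t(unclass(x)))
  n <- length(x)
  stopifnot(n >= 2L)
  denom <- sum((x - mean(x))^2)
  if (denom == 0) {
    warning("zero-variance series: intradaily variability undefined")
    return(NA_real_)
  }
  (n * sum(diff(x)^2)) / ((n - 1) * denom)
}

#' L5 and M10: least-active 5-h and most-active 10-h windows
#'
#' Scans all 24 wrap-around windows of length 5 h (L5) and 10 h (M10) on the
#' average 24-h profile and returns the minimal/maximal window means together
#' with the window start clock times. Ties break to the earliest start. The
#' profile-average convention is the default; pass a single day's profile for
#' the per-day variant.
#'
#' @param profile 24 hourly means (numeric vector), or a [day_matrix] with 24
#'   columns whose column means are used.
#' @return list: `l5`, `l5_onset_hours`, `m10`, `m10_onset_hours`.
#' @export
l5_m10 <- function(profile) {
  if (is.matrix(profile)) profile <- colMeans(unclass(profile))
  if (length(profile) != 24L)
    stop("l5_m10 expects 24 hourly values", call. = FALSE)
  wmean <- function(len) {
    sapply(0:23, function(s) mean(profile[((s + 0:(len - 1)) %% 24) + 1L]))
  }
  w5 <- wmean(5); w10 <- wmean(10)
  list(l5 = min(w5), l5_onset_hours = which.min(w5) - 1,
       m10 = max(w10), m10_onset_hours = which.max(w10) - 1)
}

#' Relative amplitude (RA)
#'
#' `RA = (M10 - L5) / (M10 + L5)`: higher values mean more differentiation
#' between day and night activity.
#'
#' @param l5,m10 window means from [l5_m10()].
#' @return RA in `[0, 1]`; `NA` with a warning when `M10 + L5 = 0`.
#' @export
relative_amplitude <- function(l5, m10) {
  if (l5 + m10 == 0) {
    warning("M10 + L5 = 0: relative amplitude undefined")
    return(NA_real_)
  }
  (m10 - l5) / (m10 + l5)
}

#' All non-parametric circadian metrics for one participant
#'
#' Convenience wrapper computing IS, IV, L5/M10 (profile-average convention),
#' RA and the circadian-band relative spectral power. The non-parametric
#' indices use hourly bins (the classical convention); the spectral measure is
#' computed at the finest resolution supplied, mirroring circadian software
#' that transforms the exported epoch-level series.
#'
#' @param dm_hourly a [day_matrix] with 24 bins per day and >= 2 days.
#' @param dm_fine optional finer-resolution [day_matrix] (e.g. raw 30-s
#'   epochs, 2880 bins/day) used for the periodogram; defaults to the hourly
#'   matrix.
#' @param band circadian period band in hours for the spectral measure.
#' @return one-row tibble: `is`, `iv`, `l5`, `l5_onset_hours`, `m10`,
#'   `m10_onset_hours`, `ra`, `fft_relpower`.
#' @export
circadian_metrics <- function(dm_hourly, dm_fine = NULL, band = c(18, 30)) {
  stopifnot(ncol(dm_hourly) == 24L)
  lm10 <- l5_m10(dm_hourly)
  dm_sp <- dm_fine %||% dm_hourly
  bin_s <- attr(dm_sp, "bin_seconds") %||% 3600
  pg <- periodogram(as.numeric(t(unclass(dm_sp))), bin_hours = bin_s / 3600)
  tibble::tibble(
    is = interdaily_stability(dm_hourly),
    iv = intradaily_variability(dm_hourly),
    l5 = lm10$l5, l5_onset_hours = lm10$l5_onset_hours,
    m10 = lm10$m10, m10_onset_hours = lm10$m10_onset_hours,
    ra = relative_amplitude(lm10$l5, lm10$m10),
    fft_relpower = fft_circadian_power(pg, band = band)
  )
}
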