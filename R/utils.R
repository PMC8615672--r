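# Small shared helpers: clock arithmetic, circular statistics, run-length tools.

#' Circular mean of clock times
#'
#' Averages times of day on the 24-h circle via the mean resultant vector, so
#' that e.g. 23:30 and 00:30 average to 00:00 rather than 12:00. Used for all
#' per-participant averaging of onsets, offsets and acrophases.
#'
#' @param hours numeric vector of clock times in hours, interpreted modulo 24.
#' @param na.rm drop missing values before averaging.
#' @return mean clock time in `[0, 24)`, or `NA` if the mean resultant vector
#'   has negligible length (antipodal inputs) or no values remain.
#' @export
circular_mean_hours <- function(hours, na.rm = TRUE) {
  if (na.rm) hours <- hours[!is.na(hours)]
  if (length(hours) == 0L) return(NA_real_)
  theta <- hours / 24 * 2 * pi
  s <- mean(sin(theta))
  c <- mean(cos(theta))
  if (sqrt(s^2 + c^2) < 1e-10) return(NA_real_)
  (atan2(s, c) / (2 * pi) * 24) %% 24
}

#' Signed shortest difference between clock times
#'
#' @param a,b clock times in hours.
#' @return `a - b` wrapped into `(-12, 12]`.
#' @export
circular_diff_hours <- function(a, b) {
  d <- (a - b) %% 24
  ifelse(d > 12, d - 24, d)
}

# Seconds past midnight of a naive local POSIXct.
clock_seconds <- function(t) {
  as.numeric(t) %% 86400
}

# Parse "HH:MM" / "HH:MM:SS" into seconds past midnight.
parse_clock <- function(x) {
  if (is.numeric(x)) return(x * 3600)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    sum(p * c(3600, 60, 1)[seq_along(p)])
  }, numeric(1))
}

# First index of a run of at least `len` TRUEs, or NA.
first_run_at_least <- function(x, len) {
  if (len <= 0L) return(if (length(x)) 1L else NA_integer_)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= len)
  if (length(hit) == 0L) return(NA_integer_)
  starts[hit[1L]]
}

# Run-length encoded runs of TRUE meeting a minimum length; returns a logical
# mask marking every epoch belonging to such a run.
mask_long_runs <- function(x, min_len) {
  r <- rle(x)
  keep <- r$values & r$lengths >= min_len
  rep(keep, r$lengths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
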