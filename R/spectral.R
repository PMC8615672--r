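# Frequency-domain rhythm strength: normalized power spectrum and the
# circadian-band relative power measure.

#' Normalized activity periodogram
#'
#' Mean-subtracts the series, computes the discrete Fourier power spectrum,
#' and normalizes each bin against the series' total non-DC energy, so
#' relative powers sum to 1 over the grid (when `pad_factor = 1`) and the
#' power of an on-grid periodic component is unchanged by zero-padding. The
#' period grid derives from the frequency bins:
#' `period_k = N_pad * bin_hours / k`.
#'
#' @param x activity series (numeric vector; hourly bins typical) or an
#'   [epoch_series()], whose epoch length sets `bin_hours`.
#' @param bin_hours sampling interval of `x` in hours.
#' @param window taper applied before the transform: `"rectangular"` (default,
#'   none) or `"hann"`.
#' @param pad_factor zero-padding factor (>= 1) refining the period grid.
#' @return list of class `periodogram`: `period_hours`, `relpower`,
#'   `peak_period_hours`, `peak_relpower`.
#' @export
periodogram <- function(x, bin_hours = 1, window = c("rectangular", "hann"),
                        pad_factor = 1) {
  if (inherits(x, "epoch_series")) {
    bin_hours <- x$epoch_length / 3600
    x <- x$activity
  }
  window <- match.arg(window)
  n <- length(x)
  if (n * bin_hours < 48)
    stop("series shorter than 48 h: the 18-30 h band is unresolvable",
         call. = FALSE)
  x <- x - mean(x)
  if (window == "hann")
    x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  ss <- sum(x^2)                             # non-DC energy before padding
  if (ss == 0) stop("constant series has no spectrum", call. = FALSE)
  n_pad <- as.integer(round(n * pad_factor))
  if (n_pad > n) x <- c(x, rep(0, n_pad - n))
  ft <- stats::fft(x)
  k <- seq_len(floor(length(x) / 2))         # non-DC bins up to Nyquist
  pow <- Mod(ft[k + 1L])^2
  rel <- 2 * pow / (n * ss)
  periods <- length(x) * bin_hours / k
  structure(list(period_hours = periods, relpower = rel,
                 peak_period_hours = periods[which.max(rel)],
                 peak_relpower = max(rel)),
            class = "periodogram")
}

#' @export
print.periodogram <- function(x, ...) {
  cat(sprintf("<periodogram> %d periods (%.2f-%.2f h); peak %.3f at %.2f h\n",
              length(x$period_hours), min(x$period_hours), max(x$period_hours),
              x$peak_relpower, x$peak_period_hours))
  invisible(x)
}

#' Circadian-band relative spectral power
#'
#' The rhythm-strength index: the maximum (default) or sum of the relative
#' non-DC power over grid periods within the circadian band (18-30 h). A
#' strongly 24-h-periodic series scores near 1; arrhythmic or purely ultradian
#' series score near 0.
#'
#' @param pgram a [periodogram()].
#' @param band period band in hours (default `c(18, 30)`).
#' @param band_mode `"peak"` (maximum relative power in the band, default) or
#'   `"integral"` (band-summed relative power).
#' @return relative power in `[0, 1]`.
#' @export
fft_circadian_power <- function(pgram, band = c(18, 30),
                                band_mode = c("peak", "integral")) {
  band_mode <- match.arg(band_mode)
  stopifnot(inherits(pgram, "periodogram"))
  sel <- pgram$period_hours >= band[1] & pgram$period_hours <= band[2]
  if (!any(sel))
    stop("no periodogram grid point falls in the requested band", call. = FALSE)
  if (band_mode == "peak") max(pgram$relpower[sel]) else sum(pgram$relpower[sel])
}
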