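#' Day-aligned activity matrix
#'
#' A rectangular `D x B` array of mean activity over `D` complete days and `B`
#' bins per day, the substrate for phase-marker detection and non-parametric
#' circadian statistics. `B = 2880` corresponds to raw 30-s epochs; `B = 24`
#' to hourly bins.
#'
#' @name day_matrix
NULL

new_day_matrix <- function(values, participant_id, bin_seconds, day_start_sec,
                           day_dates = NULL) {
  stopifnot(is.matrix(values), nrow(values) >= 1L)
  structure(values,
            participant_id = participant_id,
            bin_seconds = bin_seconds,
            day_start_sec = day_start_sec,
            day_dates = day_dates,
            class = c("day_matrix", "matrix"))
}

#' @export
print.day_matrix <- function(x, ...) {
  cat(sprintf("<day_matrix> %s: %d days x %d bins (%gs bins, day boundary %02d:%02d)\n",
              attr(x, "participant_id"), nrow(x), ncol(x), attr(x, "bin_seconds"),
              attr(x, "day_start_sec") %/% 3600,
              (attr(x, "day_start_sec") %% 3600) %/% 60))
  invisible(x)
}

#' Trim an epoch series to complete days
#'
#' Discards leading and trailing partial days relative to a configurable day
#' boundary (midnight by default: the standard actogram convention) and
#' arranges the retained epochs as a `D x B` matrix. Optionally rebins to
#' coarser bins by arithmetic mean, so trimming-then-rebinning conserves the
#' grand mean of the retained epochs exactly.
#'
#' @param series an [epoch_series()].
#' @param day_start day boundary as `"HH:MM"`/`"HH:MM:SS"` or hours; default
#'   midnight.
#' @param bins_per_day bins per day of the output; default `86400 / epoch_length`
#'   (no rebinning). Must divide the epochs-per-day count evenly.
#' @return a [day_matrix] of mean activity per bin. The attribute `day_dates`
#'   carries the calendar date on which each retained day begins.
#' @export
trim_to_full_days <- function(series, day_start = "00:00", bins_per_day = NULL) {
  stopifnot(inherits(series, "epoch_series"))
  epd <- 86400 / series$epoch_length           # epochs per day
  day_start_sec <- parse_clock(day_start)
  offs <- clock_seconds(series$start)
  # epochs until the first boundary epoch
  lead <- ((day_start_sec - offs) %% 86400) / series$epoch_length
  if (abs(lead - round(lead)) > 1e-9)
    stop("day boundary does not fall on the epoch grid", call. = FALSE)
  lead <- as.integer(round(lead))
  n <- length(series$activity)
  d <- (n - lead) %/% epd
  if (d < 1L)
    stop("series contains no complete day from the chosen boundary", call. = FALSE)
  kept <- series$activity[(lead + 1L):(lead + d * epd)]
  m <- matrix(kept, nrow = d, ncol = epd, byrow = TRUE)
  first_day <- as.Date(as.POSIXct(
    as.numeric(series$start) + lead * series$epoch_length - day_start_sec,
    origin = "1970-01-01", tz = "UTC"))
  dm <- new_day_matrix(m, series$participant_id, series$epoch_length,
                       day_start_sec, day_dates = first_day + seq_len(d) - 1L)
  if (!is.null(bins_per_day)) dm <- rebin_day_matrix(dm, bins_per_day) else dm
}

#' Rebin a day matrix to coarser bins
#'
#' @param dm a [day_matrix].
#' @param bins_per_day target number of bins per day; must divide the current
#'   bin count evenly. Cells of the result are arithmetic means of the source
#'   bins they cover.
#' @return a [day_matrix] with `bins_per_day` columns.
#' @export
rebin_day_matrix <- function(dm, bins_per_day) {
  stopifnot(inherits(dm, "day_matrix"))
  b0 <- ncol(dm)
  if (b0 %% bins_per_day != 0)
    stop("bins_per_day must divide the current bin count (", b0, ")", call. = FALSE)
  k <- b0 %/% bins_per_day
  if (k == 1L) return(dm)
  grp <- rep(seq_len(bins_per_day), each = k)
  vals <- t(apply(unclass(dm), 1L, function(r) tapply(r, grp, mean)))
  if (bins_per_day == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- NULL
  new_day_matrix(vals, attr(dm, "participant_id"),
                 attr(dm, "bin_seconds") * k, attr(dm, "day_start_sec"),
                 attr(dm, "day_dates"))
}

# Hour (fractional) of the centre of each bin, relative to midnight.
bin_centre_hours <- function(dm) {
  bs <- attr(dm, "bin_seconds")
  ((attr(dm, "day_start_sec") + (seq_len(ncol(dm)) - 0.5) * bs) / 3600) %% 24
}

# Clock hour at the leading edge of each bin.
bin_edge_hours <- function(dm) {
  bs <- attr(dm, "bin_seconds")
  ((attr(dm, "day_start_sec") + (seq_len(ncol(dm)) - 1L) * bs) / 3600) %% 24
}
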