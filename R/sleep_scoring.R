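#' Default Actiware-style scoring kernel for 30-s epochs
#'
#' Symmetric weighted-moving-average kernel: central epoch weight 2, the two
#' epochs on each side weight 1/5, the next two on each side weight 1/25. An
#' epoch is scored wake when the weighted sum of surrounding activity exceeds
#' the wake threshold (default 40, the "medium" sensitivity).
#'
#' @return numeric kernel of odd length.
#' @export
actiware_kernel <- function() {
  c(1/25, 1/25, 1/5, 1/5, 2, 1/5, 1/5, 1/25, 1/25)
}

#' Score epochs as sleep or wake
#'
#' Weighted-moving-average scorer: epoch `i` is wake iff
#' `sum(kernel * activity[neighbourhood of i]) > threshold`, with zero padding
#' at the series boundaries. This emulates the de-facto standard wrist-count
#' scoring rule for 30-s epochs; kernel and threshold are fully configurable.
#'
#' @param series an [epoch_series()] or a bare numeric activity vector.
#' @param threshold wake threshold in counts (> 0); default 40.
#' @param kernel symmetric numeric kernel of odd length.
#' @return logical vector, `TRUE` = wake, one element per epoch.
#' @export
score_epochs <- function(series, threshold = 40, kernel = actiware_kernel()) {
  x <- if (inherits(series, "epoch_series")) series$activity else as.numeric(series)
  if (length(kernel) %% 2L != 1L)
    stop("kernel length must be odd", call. = FALSE)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  if (length(kernel) > length(x))
    stop("kernel is longer than the series", call. = FALSE)
  half <- (length(kernel) - 1L) %/% 2L
  padded <- c(rep(0, half), x, rep(0, half))
  # stats::filter computes the full convolution over the padded series
  wsum <- stats::filter(padded, rev(kernel), sides = 2)
  wsum <- as.numeric(wsum)[(half + 1L):(half + length(x))]
  wsum > threshold
}

#' Resolve nightly rest intervals
#'
#' One interval per night. When a diary is present its reported bedtime and
#' wake time are used directly (with optional snapping to the nearest sustained
#' activity drop/rise within `snap_window_minutes`); without a diary the
#' template-matching phase markers supply one interval per night, pairing each
#' day's activity offset with the following day's onset.
#'
#' @param series an [epoch_series()].
#' @param diary optional `diary_record` for this participant.
#' @param snap_window_minutes half-width of the diary snapping window; 0
#'   (default) disables snapping and passes diary times through unchanged.
#' @param template_bins bins per day used for the diary-free fallback template
#'   match (6-min bins by default).
#' @return tibble with one row per night: `night`, `start`, `end` (POSIXct),
#'   `source` (`"diary"`, `"diary_snapped"` or `"auto"`).
#' @export
resolve_rest_intervals <- function(series, diary = NULL,
                                   snap_window_minutes = 0,
                                   template_bins = 240) {
  stopifnot(inherits(series, "epoch_series"))
  if (!is.null(diary)) {
    stopifnot(all(c("bedtime", "waketime") %in% names(diary)))
    start <- diary$bedtime
    end <- diary$waketime
    src <- "diary"
    if (snap_window_minutes > 0) {
      start <- vapply(start, snap_to_transition, numeric(1),
                      series = series, window_min = snap_window_minutes,
                      direction = "drop")
      end <- vapply(end, snap_to_transition, numeric(1),
                    series = series, window_min = snap_window_minutes,
                    direction = "rise")
      start <- as.POSIXct(start, origin = "1970-01-01", tz = "UTC")
      end <- as.POSIXct(end, origin = "1970-01-01", tz = "UTC")
      src <- "diary_snapped"
    }
    out <- tibble::tibble(night = seq_along(start), start = start, end = end,
                          source = src)
  } else {
    dm <- trim_to_full_days(series, bins_per_day = template_bins)
    off <- template_match_offsets(dm)$per_day
    on <- template_match_onsets(dm)$per_day
    dates <- attr(dm, "day_dates")
    nights <- seq_len(nrow(dm) - 1L)
    start <- as.POSIXct(paste(dates[nights]), tz = "UTC") +
      off$offset_hours[nights] * 3600
    end <- as.POSIXct(paste(dates[nights + 1L]), tz = "UTC") +
      on$onset_hours[nights + 1L] * 3600
    keep <- !is.na(start) & !is.na(end) & end > start
    out <- tibble::tibble(night = nights[keep], start = start[keep],
                          end = end[keep], source = "auto")
  }
  if (nrow(out) > 1L && any(out$start[-1L] < out$end[-nrow(out)]))
    stop("rest intervals overlap", call. = FALSE)
  out
}

# Snap a diary time (POSIXct) to the steepest sustained activity transition
# within +/- window_min minutes; returns numeric seconds since epoch.
snap_to_transition <- function(t0, series, window_min, direction) {
  times <- as.numeric(epoch_times(series))
  sm_n <- max(1L, as.integer(round(600 / series$epoch_length)))  # 10-min mean
  sm <- as.numeric(stats::filter(series$activity, rep(1 / sm_n, sm_n), sides = 2))
  idx <- which(abs(times - as.numeric(t0)) <= window_min * 60)
  idx <- idx[idx > sm_n & idx <= length(sm) - sm_n]
  if (length(idx) < 2L) return(as.numeric(t0))
  slope <- sm[idx + 1L] - sm[idx]
  pick <- if (direction == "drop") idx[which.min(slope)] else idx[which.max(slope)]
  if (is.na(sm[pick])) return(as.numeric(t0))
  times[pick]
}

#' Summarize sleep within rest intervals
#'
#' Per night: sleep onset is the start of the first run of at least
#' `onset_rule_minutes` consecutive sleep-scored minutes inside the interval;
#' TST is the sleep-scored minutes in the whole interval; WASO the wake-scored
#' minutes between sleep onset and interval end; SE is `100 * TST / duration`.
#' The identity `TST + WASO + pre-onset wake = duration` holds exactly every
#' night. Per-participant values are plain means over retained nights.
#'
#' @param labels logical wake labels from [score_epochs()], one per epoch.
#' @param intervals rest intervals from [resolve_rest_intervals()].
#' @param series the scored [epoch_series()] (for the epoch grid).
#' @param onset_rule_minutes consecutive sleep minutes defining onset
#'   (default 10).
#' @return list of class `sleep_summary`: `per_night` tibble (`night`,
#'   `onset_time`, `duration_min`, `tst_min`, `waso_min`, `pre_onset_wake_min`,
#'   `se_pct`, `flagged`) and `participant` one-row tibble of means over
#'   unflagged nights.
#' @export
summarize_sleep <- function(labels, intervals, series, onset_rule_minutes = 10) {
  stopifnot(inherits(series, "epoch_series"),
            length(labels) == length(series$activity))
  epm <- 60 / series$epoch_length                 # epochs per minute
  onset_epochs <- as.integer(round(onset_rule_minutes * epm))
  t0 <- as.numeric(series$start)
  el <- series$epoch_length
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    a <- as.numeric(intervals$start[i])
    b <- as.numeric(intervals$end[i])
    i0 <- as.integer(ceiling((a - t0) / el)) + 1L
    i1 <- as.integer(floor((b - t0) / el))        # epochs fully inside
    i0 <- max(i0, 1L); i1 <- min(i1, length(labels))
    if (i1 < i0) return(NULL)
    wake <- labels[i0:i1]
    onset_rel <- first_run_at_least(!wake, onset_epochs)
    dur_min <- length(wake) / epm
    if (is.na(onset_rel)) {
      return(tibble::tibble(night = intervals$night[i],
                            onset_time = as.POSIXct(NA, tz = "UTC"),
                            duration_min = dur_min, tst_min = NA_real_,
                            waso_min = NA_real_, pre_onset_wake_min = NA_real_,
                            se_pct = NA_real_, flagged = TRUE))
    }
    tst <- sum(!wake) / epm
    waso <- sum(wake[onset_rel:length(wake)]) / epm
    pre <- sum(wake[seq_len(onset_rel - 1L)]) / epm
    tibble::tibble(night = intervals$night[i],
                   onset_time = series$start + (i0 + onset_rel - 2L) * el,
                   duration_min = dur_min, tst_min = tst, waso_min = waso,
                   pre_onset_wake_min = pre,
                   se_pct = 100 * tst / dur_min, flagged = FALSE)
  })
  per_night <- dplyr::bind_rows(rows)
  ok <- per_night[!per_night$flagged, , drop = FALSE]
  participant <- tibble::tibble(
    participant_id = series$participant_id,
    n_nights = nrow(ok),
    tst_min = mean(ok$tst_min),
    waso_min = mean(ok$waso_min),
    se_pct = mean(ok$se_pct),
    sleep_onset_hours = circular_mean_hours(clock_seconds(ok$onset_time) / 3600)
  )
  structure(list(per_night = per_night, participant = participant),
            class = "sleep_summary")
}
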