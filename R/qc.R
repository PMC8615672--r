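#' Quality-control inclusion verdict for an actigraphy recording
#'
#' Applies the study-style inclusion rules: a participant is retained only if
#' at least `min_days` consecutive complete 24-h days survive day alignment.
#' The verdict additionally flags night-only wear (daytime epochs dominated by
#' long zero-count runs or off-wrist flags) and recordings overlapping listed
#' daylight-saving transition dates. Always returns a verdict; never errors.
#'
#' A recorded day counts as "worn" when fewer than `worn_zero_frac` of its
#' daytime epochs (between `daytime_window` clock hours) belong to zero-count
#' runs of at least `zero_run_minutes` or are off-wrist-flagged. A participant
#' is excluded as a night-only wearer when more than `max_unworn_days`
#' recorded days fail that test. Both thresholds are configurable because the
#' underlying field rules ("wore the watch at night only", "extended periods"
#' of removal) are qualitative.
#'
#' @param series an [epoch_series()].
#' @param diary optional `diary_record` (currently unused by the rules, kept
#'   for interface stability).
#' @param min_days minimum number of consecutive complete days (default 5).
#' @param day_start day boundary passed to [trim_to_full_days()].
#' @param daytime_window clock hours delimiting "daytime" (default 08-20).
#' @param zero_run_minutes minimum zero-run length treated as non-wear.
#' @param worn_zero_frac maximum tolerated non-wear fraction of daytime epochs.
#' @param max_unworn_days days allowed to fail the wear test before exclusion.
#' @param dst_dates optional Dates of daylight-saving transitions; overlap
#'   raises a flag (not an exclusion).
#' @return a list of class `qc_verdict`: `include` (logical), `reasons`
#'   (character reason codes, empty when included), `flags`, `n_complete_days`,
#'   `n_unworn_days`.
#' @export
qc_inclusion <- function(series, diary = NULL, min_days = 5,
                         day_start = "00:00", daytime_window = c(8, 20),
                         zero_run_minutes = 30, worn_zero_frac = 0.2,
                         max_unworn_days = 1, dst_dates = NULL) {
  stopifnot(inherits(series, "epoch_series"))
  reasons <- character()
  flags <- character()

  n_days <- tryCatch(nrow(trim_to_full_days(series, day_start)),
                     error = function(e) 0L)
  if (n_days < min_days) reasons <- c(reasons, "insufficient_days")

  # night-only wear: evaluate every recorded day with daytime coverage
  times <- epoch_times(series)
  hour <- clock_seconds(times) / 3600
  day_id <- as.Date(times)
  daytime <- hour >= daytime_window[1] & hour < daytime_window[2]
  min_run <- as.integer(round(zero_run_minutes * 60 / series$epoch_length))
  nonwear <- mask_long_runs(series$activity == 0, min_run)
  if (!is.null(series$off_wrist)) nonwear <- nonwear | series$off_wrist
  epd_day <- (daytime_window[2] - daytime_window[1]) * 3600 / series$epoch_length
  unworn_by_day <- tapply(seq_along(hour), day_id, function(idx) {
    idx <- idx[daytime[idx]]
    if (length(idx) < epd_day) return(NA)      # partial daytime coverage
    mean(nonwear[idx]) >= worn_zero_frac
  })
  n_unworn <- sum(unlist(unworn_by_day), na.rm = TRUE)
  if (n_unworn > max_unworn_days) reasons <- c(reasons, "night_only_wear")

  if (!is.null(dst_dates) &&
      any(as.Date(dst_dates) %in% unique(day_id)))
    flags <- c(flags, "dst_transition_in_window")

  structure(list(include = length(reasons) == 0L,
                 reasons = reasons, flags = flags,
                 n_complete_days = n_days,
                 n_unworn_days = as.integer(n_unworn)),
            class = "qc_verdict")
}

#' @export
print.qc_verdict <- function(x, ...) {
  cat(sprintf("<qc_verdict> %s (%d complete days)%s%s\n",
              if (x$include) "include" else "exclude", x$n_complete_days,
              if (length(x$reasons)) paste0(" reasons: ", paste(x$reasons, collapse = ", ")) else "",
              if (length(x$flags)) paste0(" flags: ", paste(x$flags, collapse = ", ")) else ""))
  invisible(x)
}
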