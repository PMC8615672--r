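# End-to-end orchestration: io -> QC -> scoring -> phase -> NPCRA -> spectral
# -> cohort table -> group summaries and contrasts.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with its default.
#'
#' @param day_start day boundary (`"HH:MM"`), default midnight.
#' @param min_days QC minimum consecutive complete days.
#' @param threshold,onset_rule_minutes,snap_window_minutes sleep-scoring
#'   tunables (wake threshold in counts; consecutive sleep minutes defining
#'   onset; diary snapping half-window, 0 = off).
#' @param template_bins bins per day for template phase matching (6-min bins).
#' @param npcra_bins bins per day for the non-parametric metrics (hourly).
#' @param band circadian period band (h) for the spectral measure.
#' @param band_mode `"peak"` or `"integral"` band summary.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(day_start = "00:00", min_days = 5,
                            threshold = 40, onset_rule_minutes = 10,
                            snap_window_minutes = 0, template_bins = 240,
                            npcra_bins = 24, band = c(18, 30),
                            band_mode = "peak") {
  structure(as.list(environment()), class = "pipeline_config")
}

#' All per-participant measures from one recording
#'
#' Runs the full measurement chain for one participant: day alignment,
#' weighted-moving-average sleep scoring inside diary-anchored rest intervals,
#' template-matching onsets/offsets, cosinor MESOR/amplitude/acrophase,
#' the non-parametric circadian metrics and the circadian-band spectral
#' power.
#'
#' @param series an [epoch_series()].
#' @param diary optional `diary_record` for this participant.
#' @param config a [pipeline_config()].
#' @return one-row tibble of participant-level measures.
#' @export
participant_metrics <- function(series, diary = NULL,
                                config = pipeline_config()) {
  dm_e <- trim_to_full_days(series, config$day_start)   # native epoch bins
  dm_t <- rebin_day_matrix(dm_e, config$template_bins)
  dm_h <- rebin_day_matrix(dm_e, config$npcra_bins)
  labels <- score_epochs(series, threshold = config$threshold)
  intervals <- resolve_rest_intervals(series, diary,
                                      snap_window_minutes = config$snap_window_minutes,
                                      template_bins = config$template_bins)
  sleep <- summarize_sleep(labels, intervals, series,
                           onset_rule_minutes = config$onset_rule_minutes)
  on <- template_match_onsets(dm_t)
  off <- template_match_offsets(dm_t)
  cos <- cosinor_fit(dm_h)
  met <- circadian_metrics(dm_h, dm_fine = dm_e, band = config$band)
  tibble::tibble(
    participant_id = series$participant_id,
    n_days = nrow(dm_h),
    n_nights = sleep$participant$n_nights,
    tst_min = sleep$participant$tst_min,
    se_pct = sleep$participant$se_pct,
    waso_min = sleep$participant$waso_min,
    onset_hours = on$mean_hours,
    offset_hours = off$mean_hours,
    acrophase_hours = cos$acrophase_hours,
    mesor = cos$mesor,
    amplitude = cos$amplitude,
    is = met$is, iv = met$iv,
    l5 = met$l5, m10 = met$m10, ra = met$ra,
    l5_onset_hours = met$l5_onset_hours, m10_onset_hours = met$m10_onset_hours,
    fft_relpower = met$fft_relpower
  )
}

#' Run the full cohort pipeline
#'
#' Applies QC to every participant, computes all measures for those included,
#' joins the cohort information table, and produces the group-by-age summary
#' and DS-vs-TD / age-shift contrasts. A pure function of (inputs, config).
#'
#' @param cohort either the output of [generate_cohort()] or a directory
#'   containing `epochs_<id>.csv` files, `diary.csv` and `cohort.csv` as
#'   written by [write_cohort_csvs()].
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `cohort_table` (one row per
#'   included participant: measures + cohort covariates), `group_summary`,
#'   `contrasts`, `qc` (tibble of verdicts).
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  if (is.character(cohort)) cohort <- read_cohort_csvs(cohort)
  parts <- cohort$participants
  qc_rows <- list(); met_rows <- list()
  for (pid in names(parts)) {
    p <- parts[[pid]]
    v <- qc_inclusion(p$series, p$diary, min_days = config$min_days,
                      day_start = config$day_start)
    qc_rows[[pid]] <- tibble::tibble(
      participant_id = pid, include = v$include,
      n_complete_days = v$n_complete_days,
      reasons = paste(v$reasons, collapse = ";"))
    if (v$include)
      met_rows[[pid]] <- participant_metrics(p$series, p$diary, config)
  }
  qc <- dplyr::bind_rows(qc_rows)
  if (length(met_rows) == 0L)
    stop("all participants fail QC: ",
         paste(unique(qc$reasons[qc$reasons != ""]), collapse = ", "),
         call. = FALSE)
  metrics <- dplyr::bind_rows(met_rows)
  cohort_table <- dplyr::left_join(metrics, cohort$info, by = "participant_id")
  gs <- group_summary(cohort_table)
  structure(list(cohort_table = cohort_table,
                 group_summary = gs,
                 contrasts = derive_group_contrasts(gs),
                 qc = qc),
            class = "pipeline_result")
}

#' Read a cohort directory written by [write_cohort_csvs()]
#'
#' @param dir directory path.
#' @return list with `participants` (series + diary per id) and `info`.
#' @export
read_cohort_csvs <- function(dir) {
  files <- list.files(dir, pattern = "^epochs_.*\\.csv$", full.names = TRUE)
  if (length(files) == 0L) stop("no epoch CSVs found in ", dir, call. = FALSE)
  diary_all <- if (file.exists(file.path(dir, "diary.csv")))
    read_diary_csv(file.path(dir, "diary.csv")) else NULL
  participants <- list()
  for (f in files) {
    s <- read_epoch_csv(f)
    pid <- sub("^epochs_", "", s$participant_id)
    s$participant_id <- pid
    d <- if (!is.null(diary_all))
      diary_all[diary_all$participant_id == pid, , drop = FALSE] else NULL
    participants[[pid]] <- list(series = s, diary = d)
  }
  info <- if (file.exists(file.path(dir, "cohort.csv")))
    readr::read_csv(file.path(dir, "cohort.csv"), show_col_types = FALSE,
                    progress = FALSE) else NULL
  list(participants = participants, info = info)
}

# Measures summarized per group x age cell.
standard_measures <- function() {
  c("tst_min", "se_pct", "waso_min", "onset_hours", "offset_hours",
    "acrophase_hours", "is", "iv", "fft_relpower", "l5", "m10")
}

#' Group-by-age summary of cohort measures
#'
#' Clock-time measures (onsets, offsets, acrophase) are averaged on the 24-h
#' circle: participants whose phase straddles midnight would otherwise drag an
#' arithmetic mean toward midday. Their SD is the circular standard deviation
#' mapped to hours.
#'
#' @param cohort_table output table of [run_pipeline()].
#' @param measures measure columns to summarize.
#' @return tidy tibble: `measure`, `group`, `age_group`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(cohort_table, measures = standard_measures()) {
  measures <- intersect(measures, names(cohort_table))
  units <- measure_units()
  long <- tidyr::pivot_longer(
    cohort_table[, c("group", "age_group", measures)],
    dplyr::all_of(measures), names_to = "measure", values_to = "value")
  circ_sd_hours <- function(h) {
    h <- h[!is.na(h)]
    if (length(h) < 2L) return(NA_real_)
    theta <- h / 24 * 2 * pi
    r <- sqrt(mean(sin(theta))^2 + mean(cos(theta))^2)
    sqrt(pmax(0, -2 * log(r))) * 24 / (2 * pi)
  }
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$measure, .data$group, .data$age_group),
    n = sum(!is.na(.data$value)),
    mean = if (isTRUE(units[.data$measure[1]] == "h"))
      circular_mean_hours(.data$value) else mean(.data$value, na.rm = TRUE),
    sd = if (isTRUE(units[.data$measure[1]] == "h"))
      circ_sd_hours(.data$value) else stats::sd(.data$value, na.rm = TRUE),
    .groups = "drop")
  out$measure <- factor(out$measure, levels = measures)
  dplyr::arrange(out, .data$measure, .data$age_group, .data$group)
}

#' Group and age-shift contrasts from a group summary
#'
#' Two families of derived contrasts, reported at printed precision (percent
#' and minutes to integers) alongside full-precision differences:
#' `group_within_age` rows give `DS - TD` per measure and age band (percent
#' difference `100 * (DS - TD) / TD`); `age_within_group` rows give the
#' adolescent-vs-child and adult-vs-adolescent shifts within each diagnostic
#' group. Differences in hour-valued measures are also expressed in minutes.
#' Cells missing either side are omitted.
#'
#' @param gs a [group_summary()] (or [reference_cohort_summary()] reshaped by
#'   [reference_summary_long()]).
#' @return tibble: `contrast`, `measure`, `age_group`/`group`, `comparison`,
#'   `mean_a`, `mean_b`, `diff`, `pct_diff`, `diff_minutes`.
#' @export
derive_group_contrasts <- function(gs) {
  units <- measure_units()
  wide <- tidyr::pivot_wider(gs[, c("measure", "group", "age_group", "mean")],
                             names_from = "group", values_from = "mean")
  rows <- list()
  cdiff <- function(a, b, meas) {
    h <- units[as.character(meas)] %in% "h"
    ifelse(h, circular_diff_hours(a, b), a - b)
  }
  if (all(c("DS", "TD") %in% names(wide))) {
    ok <- !is.na(wide$DS) & !is.na(wide$TD)
    w <- wide[ok, ]
    diff <- cdiff(w$DS, w$TD, w$measure)
    to_min <- ifelse(units[as.character(w$measure)] %in% "h", 60, 1)
    rows$group <- tibble::tibble(
      contrast = "group_within_age", measure = as.character(w$measure),
      stratum = as.character(w$age_group), comparison = "DS_vs_TD",
      mean_a = w$DS, mean_b = w$TD, diff = diff,
      pct_diff = round(100 * diff / w$TD),
      diff_minutes = round(diff * to_min))
  }
  shifts <- list(c("adolescent", "child"), c("adult", "adolescent"))
  byg <- tidyr::pivot_wider(gs[, c("measure", "group", "age_group", "mean")],
                            names_from = "age_group", values_from = "mean")
  for (sh in shifts) {
    if (!all(sh %in% names(byg))) next
    ok <- !is.na(byg[[sh[1]]]) & !is.na(byg[[sh[2]]])
    w <- byg[ok, ]
    diff <- cdiff(w[[sh[1]]], w[[sh[2]]], w$measure)
    to_min <- ifelse(units[as.character(w$measure)] %in% "h", 60, 1)
    rows[[paste(sh, collapse = "_")]] <- tibble::tibble(
      contrast = "age_within_group", measure = as.character(w$measure),
      stratum = as.character(w$group),
      comparison = paste0(sh[1], "_vs_", sh[2]),
      mean_a = w[[sh[1]]], mean_b = w[[sh[2]]], diff = diff,
      pct_diff = round(100 * diff / w[[sh[2]]]),
      diff_minutes = round(diff * to_min))
  }
  dplyr::bind_rows(rows)
}

#' Reference summary reshaped to the tidy group-summary layout
#'
#' Reshapes [reference_cohort_summary()] into the same tidy form
#' [group_summary()] produces, so [derive_group_contrasts()] can run on the
#' published means.
#'
#' @return tibble: `measure`, `group`, `age_group`, `n`, `mean`, `sd`.
#' @export
reference_summary_long <- function() {
  ref <- reference_cohort_summary()
  meas <- sub("_mean$", "", grep("_mean$", names(ref), value = TRUE))
  rows <- lapply(meas, function(m) {
    tibble::tibble(measure = m, group = ref$group, age_group = ref$age_group,
                   n = ref$n, mean = ref[[paste0(m, "_mean")]],
                   sd = ref[[paste0(m, "_sd")]])
  })
  dplyr::bind_rows(rows)
}
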