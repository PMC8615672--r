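# Six group presets calibrated so that the full pipeline (weighted-moving-
# average scoring inside diary rest intervals, template phase markers, NPCRA,
# epoch-resolution periodogram) run on generated cohorts reproduces the
# reference cohort summary means (reference_cohort_summary()). Derived
# anchors: rest-interval duration = TST / (SE/100); the wind-down start,
# wind-down/lie-in durations and settling minutes absorb the template and
# scorer estimator offsets so the *measured* onset/offset/SE means land on
# the printed values. Night-to-night phase jitter carries the interdaily-
# stability level; the hourly behavioural factor carries intradaily
# variability; epoch-count dispersion carries the circadian-band relative
# power.

#' Reference-calibrated simulator presets
#'
#' Returns the six [group_params()] presets (DS/TD x child/adolescent/adult)
#' calibrated against [reference_cohort_summary()]. Group sizes default to
#' the reference study's (20/20/28/13/10/10).
#'
#' @param n_override optional single group size applied to every preset
#'   (e.g. 50 for calibration ensembles).
#' @return named list of [group_params()].
#' @export
reference_presets <- function(n_override = NULL) {
  presets <- list(
    child_DS = group_params(
      label = "child_DS", group = "DS", age_group = "child", n = 20,
      age_range = c(6, 10),
      offset_mean = 21.15, offset_sd_between = 0.60, offset_sd_night = 0.69,
      interval_min = 559.8, interval_sd_between = 25, interval_sd_night = 18,
      wind_down_min = 1.2, lie_in_min = 0.8, latency_min = 9.5,
      sleep_lambda = 1.2, arousal_rate = 12.2, arousal_dur_min = 6,
      arousal_amp = 180,
      day_mean = 558, day_shape = 3.4, env_amp = 0.10, acrophase_h = 12.7,
      hour_sd = 0.19, hour_ar = 0.45, ultradian_amp = 0.15),
    child_TD = group_params(
      label = "child_TD", group = "TD", age_group = "child", n = 20,
      age_range = c(6, 10),
      offset_mean = 20.73, offset_sd_between = 0.80, offset_sd_night = 0.71,
      interval_min = 540.1, interval_sd_between = 25, interval_sd_night = 18,
      wind_down_min = 42.3, lie_in_min = 28.2, latency_min = 6.8,
      sleep_lambda = 1.3, arousal_rate = 7.7, arousal_dur_min = 6,
      arousal_amp = 170,
      day_mean = 630, day_shape = 2.6, env_amp = 0.10, acrophase_h = 12.8,
      hour_sd = 0.33, hour_ar = 0.45, ultradian_amp = 0.15),
    adolescent_DS = group_params(
      label = "adolescent_DS", group = "DS", age_group = "adolescent", n = 28,
      age_range = c(11, 18),
      offset_mean = 21.42, offset_sd_between = 1.00, offset_sd_night = 0.38,
      interval_min = 509.8, interval_sd_between = 30, interval_sd_night = 22,
      wind_down_min = 1.2, lie_in_min = 0.8, latency_min = 9.7,
      sleep_lambda = 0.1, arousal_rate = 9.4, arousal_dur_min = 6,
      arousal_amp = 180,
      day_mean = 363, day_shape = 3.0, env_amp = 0.10, acrophase_h = 15.9,
      hour_sd = 0.34, hour_ar = 0.45, ultradian_amp = 0.15),
    adolescent_TD = group_params(
      label = "adolescent_TD", group = "TD", age_group = "adolescent", n = 13,
      age_range = c(11, 18),
      offset_mean = 23.10, offset_sd_between = 1.30, offset_sd_night = 0.49,
      interval_min = 490.5, interval_sd_between = 30, interval_sd_night = 22,
      wind_down_min = 1.2, lie_in_min = 0.8, latency_min = 3.8,
      sleep_lambda = 1.9, arousal_rate = 6.6, arousal_dur_min = 6,
      arousal_amp = 170,
      day_mean = 336, day_shape = 1.7, env_amp = 0.10, acrophase_h = 15.2,
      hour_sd = 0.47, hour_ar = 0.45, ultradian_amp = 0.15),
    adult_DS = group_params(
      label = "adult_DS", group = "DS", age_group = "adult", n = 10,
      age_range = c(19, 26),
      offset_mean = 22.64, offset_sd_between = 1.20, offset_sd_night = 0.63,
      interval_min = 476.1, interval_sd_between = 30, interval_sd_night = 22,
      wind_down_min = 2.5, lie_in_min = 1.7, latency_min = 11.4,
      sleep_lambda = 0.1, arousal_rate = 10.1, arousal_dur_min = 6,
      arousal_amp = 190,
      day_mean = 327, day_shape = 6.6, env_amp = 0.10, acrophase_h = 13.1,
      hour_sd = 0.41, hour_ar = 0.45, ultradian_amp = 0.15),
    adult_TD = group_params(
      label = "adult_TD", group = "TD", age_group = "adult", n = 10,
      age_range = c(19, 26),
      offset_mean = 22.67, offset_sd_between = 2.00, offset_sd_night = 0.90,
      interval_min = 430.5, interval_sd_between = 30, interval_sd_night = 22,
      wind_down_min = 46.7, lie_in_min = 31.2, latency_min = 16.0,
      sleep_lambda = 2.6, arousal_rate = 5.9, arousal_dur_min = 6,
      arousal_amp = 180,
      day_mean = 345, day_shape = 1.8, env_amp = 0.10, acrophase_h = 18.5,
      hour_sd = 0.39, hour_ar = 0.45, ultradian_amp = 0.15)
  )
  if (!is.null(n_override))
    presets <- lapply(presets, function(p) { p$n <- n_override; p })
  presets
}
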