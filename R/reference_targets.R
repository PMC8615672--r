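#' Reference cohort summary statistics
#'
#' Published group means (and SDs) of the sleep, phase and circadian measures
#' from a cross-sectional actigraphy study of Down syndrome (DS) and typically
#' developing (TD) participants in three age bands (children 6-10, adolescents
#' 11-18, young adults 19-26). These are the calibration targets of the
#' [reference_presets()] simulator presets and the reference input for
#' [derive_group_contrasts()] arithmetic.
#'
#' Units: `tst_min` and `waso_min` minutes; `se_pct` percent; `onset_hours`,
#' `offset_hours`, `acrophase_hours` clock hours; `is`, `iv`, `fft_relpower`
#' dimensionless; `l5`, `m10` mean counts per 30-s epoch over the least/most
#' active window.
#'
#' @return tibble: `group`, `age_group`, `n`, then `<measure>_mean` and
#'   `<measure>_sd` columns.
#' @export
reference_cohort_summary <- function() {
  tibble::tribble(
    ~group, ~age_group, ~n,
    ~tst_min_mean, ~tst_min_sd, ~se_pct_mean, ~se_pct_sd,
    ~waso_min_mean, ~waso_min_sd,
    ~onset_hours_mean, ~onset_hours_sd, ~offset_hours_mean, ~offset_hours_sd,
    ~acrophase_hours_mean, ~acrophase_hours_sd,
    ~is_mean, ~is_sd, ~iv_mean, ~iv_sd, ~fft_relpower_mean, ~fft_relpower_sd,
    ~l5_mean, ~l5_sd, ~m10_mean, ~m10_sd,
    "DS", "child",      20, 469.37, 51.59, 83.85, 5.05, 83.18, 24.93,
      6.69, 0.60, 20.76, 0.77, 13.62, 0.87,
      0.80, 0.09, 0.53, 0.141, 0.31, 0.07, 22.53, 10.93, 614.73, 171.56,
    "TD", "child",      20, 482.40, 40.43, 89.32, 2.68, 53.23, 13.01,
      7.014, 1.140, 20.48, 0.96, 13.59, 0.83,
      0.71, 0.08, 0.64, 0.14, 0.27, 0.06, 13.76, 5.02, 687.0, 107.28,
    "DS", "adolescent", 28, 438.32, 53.40, 85.98, 3.37, 64.74, 16.80,
      6.59, 1.08, 20.92, 1.21, 14.16, 1.04,
      0.71, 0.09, 0.72, 0.19, 0.22, 0.06, 17.64, 6.08, 403.75, 110.36,
    "TD", "adolescent", 13, 439.61, 66.73, 89.63, 2.62, 46.86, 18.91,
      7.57, 1.21, 22.23, 1.59, 14.88, 1.54,
      0.58, 0.17, 0.85, 0.22, 0.14, 0.06, 14.94, 14.89, 376.74, 138.78,
    "DS", "adult",      10, 398.61, 55.83, 83.73, 6.67, 69.11, 34.71,
      7.19, 1.24, 21.83, 1.47, 14.30, 1.30,
      0.60, 0.14, 0.81, 0.26, 0.23, 0.17, 23.00, 15.30, 363.89, 122.82,
    "TD", "adult",      10, 376.12, 51.49, 87.36, 3.52, 41.27, 10.96,
      7.80, 2.97, 22.40, 3.53, 15.82, 1.80,
      0.59, 0.11, 0.77, 0.22, 0.15, 0.040, 18.53, 10.72, 376.69, 62.81
  )
}

# Units of each cohort measure, used when reporting contrasts.
measure_units <- function() {
  c(tst_min = "min", waso_min = "min", se_pct = "pct",
    onset_hours = "h", offset_hours = "h", acrophase_hours = "h",
    is = "", iv = "", ra = "", fft_relpower = "",
    l5 = "counts", m10 = "counts")
}
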