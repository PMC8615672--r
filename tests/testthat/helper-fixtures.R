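# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# Epoch series with a square-wave day: `active` counts between wake_h and
# sleep_h clock hours, `rest` counts otherwise. Starts at midnight.
square_wave_series <- function(days = 6, wake_h = 7, sleep_h = 21,
                               active = 600, rest = 0, epoch_length = 30,
                               start = "2024-03-04 00:00:00",
                               participant_id = "sq") {
  epd <- 86400 / epoch_length
  hour <- ((seq_len(epd) - 1) * epoch_length) / 3600
  day <- ifelse(hour >= wake_h & hour < sleep_h, active, rest)
  epoch_series(rep(day, days), start, epoch_length, participant_id)
}

# Hourly day_matrix from a vector of 24 values repeated over D days.
tiled_day_matrix <- function(profile24, days = 6) {
  s <- epoch_series(rep(rep(profile24, each = 120), days),
                    "2024-03-04 00:00:00", 30, "tile")
  trim_to_full_days(s, bins_per_day = 24)
}

# Deterministic group parameterization: no jitter, no arousals, no noise.
# Downstream interdaily stability is exactly 1 and WASO exactly 0.
deterministic_params <- function(...) {
  group_params(
    label = "det", group = "TD", age_group = "child", n = 1, nights = 7,
    offset_mean = 21, offset_sd_between = 0, offset_sd_night = 0,
    interval_min = 540, interval_sd_between = 0, interval_sd_night = 0,
    schedule_jitter_min = 0,
    wind_down_min = 30, lie_in_min = 15, latency_min = 0, settle_mean = 0,
    quiet_mean = 0, sleep_lambda = 0,
    arousal_rate = 0, arousal_dur_min = 6, arousal_amp = 0,
    day_mean = 500, day_shape = Inf, env_amp = 0.2, acrophase_h = 14,
    hour_sd = 0, hour_ar = 0, ultradian_amp = 0,
    edge_boost = 1, edge_boost_min = 0, ...)
}

# Small two-factor cohort for the statistics module.
toy_cohort <- function(n_per_cell = 10, effect = 0, seed = 1) {
  set.seed(seed)
  g <- expand.grid(group = c("DS", "TD"),
                   age_group = c("child", "adolescent", "adult"),
                   rep = seq_len(n_per_cell))
  g$y <- stats::rnorm(nrow(g)) + effect * (g$group == "DS")
  g
}
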