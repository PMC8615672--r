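# Synthetic actogram cohort generator. Every downstream stage of the package
# is exercised against data from this module, whose ground truth (nightly rest
# windows, arousal minutes, phases, planted regression coefficients) is known
# exactly and fully determined by the seed.
#
# Nightly structure, per participant:
#   ... daytime activity | wind-down (quiet, pre-bed) | in bed: settling
#   (wake) -> sleep with Poisson-placed arousal bouts -> wake time | lie-in
#   (quiet, in bed awake) | daytime ...
# The wind-down start is what the offset template detects; the end of the
# lie-in (activity resumption) is what the onset template detects; the diary
# records the in-bed window, whose duration together with settling and
# detected arousal minutes fixes TST, SE and WASO.

# Gamma draw parameterized by mean; shape = Inf gives the deterministic mean.
rgamma_mean <- function(n, mean, shape) {
  if (n == 0L) return(numeric(0))
  if (mean <= 0) return(rep(0, n))
  if (!is.finite(shape)) return(rep(mean, n))
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Simulation parameters for one participant group
#'
#' Defines the data-generating conditions of a group (diagnosis x age band):
#' sleep timing and its between-participant and night-to-night jitter,
#' nocturnal arousal bouts (which drive WASO and L5), daytime activity level
#' and dispersion, the diurnal envelope, and hour-scale behavioural
#' variability (which drives IV). All clock times are hours, durations
#' minutes, activity in counts per 30-s epoch.
#'
#' @param label group label.
#' @param group diagnostic group (`"DS"`/`"TD"`).
#' @param age_group age band (`"child"`, `"adolescent"`, `"adult"`).
#' @param n participants per group.
#' @param nights nights recorded per participant (>= 5 so QC passes).
#' @param age_range continuous-age range (years).
#' @param offset_mean mean clock time of the evening activity offset
#'   (wind-down start), in `[12, 30)`: values at or above 24 place the
#'   wind-down after midnight.
#' @param offset_sd_between,offset_sd_night between-participant and nightly
#'   SD of the offset (h).
#' @param interval_min mean in-bed (rest interval) duration (min).
#' @param interval_sd_between,interval_sd_night its SDs (min).
#' @param schedule_jitter_min nightly SD (min) of the wind-down, lie-in and
#'   settling durations; 0 gives a perfectly regular schedule.
#' @param wind_down_min quiet pre-bed period (min): offset-to-bedtime.
#' @param lie_in_min quiet post-wake period (min): wake-to-activity-onset.
#' @param latency_min settling (scored wake) minutes at bed start.
#' @param settle_mean mean counts/epoch while settling.
#' @param quiet_mean mean counts/epoch during wind-down/lie-in.
#' @param sleep_lambda Poisson mean counts/epoch asleep.
#' @param arousal_rate mean arousal bouts per night.
#' @param arousal_dur_min mean bout duration (min).
#' @param arousal_amp mean counts/epoch during a bout.
#' @param day_mean mean daytime counts/epoch (before envelope).
#' @param day_shape gamma shape of epoch counts (`Inf` = deterministic).
#' @param env_amp relative amplitude of the diurnal envelope.
#' @param acrophase_h clock hour of the envelope peak.
#' @param hour_sd stationary lognormal sdlog of the per-hour behavioural
#'   factor (hour-scale fragmentation; the IV dial).
#' @param hour_ar AR(1) coefficient of the log hourly factor across
#'   consecutive hours (smoothness of behavioural drift).
#' @param ultradian_amp relative amplitude of the within-day ultradian
#'   modulation of waking activity.
#' @param ultradian_period_h ultradian period (h), random phase per
#'   participant (a clock-locked daily routine).
#' @param edge_boost multiplicative activity elevation during the morning
#'   rise and evening pre-wind-down routines (getting up, chores); sharpens
#'   the rest-activity transitions the way real actograms show them.
#' @param edge_boost_min duration (min) of each transition routine.
#' @param seed_offset constant mixed into per-participant seeds.
#' @return list of class `group_params`.
#' @export
group_params <- function(label = "group", group = "TD", age_group = "child",
                         n = 20, nights = 7, age_range = c(6, 10),
                         offset_mean = 20.8, offset_sd_between = 0.6,
                         offset_sd_night = 0.4,
                         interval_min = 550, interval_sd_between = 25,
                         interval_sd_night = 20, schedule_jitter_min = 3,
                         wind_down_min = 30, lie_in_min = 15,
                         latency_min = 6, settle_mean = 120,
                         quiet_mean = 10, sleep_lambda = 1.5,
                         arousal_rate = 8, arousal_dur_min = 6,
                         arousal_amp = 180,
                         day_mean = 600, day_shape = 1.2,
                         env_amp = 0.3, acrophase_h = 13.6,
                         hour_sd = 0.5, hour_ar = 0.6,
                         ultradian_amp = 0.25, ultradian_period_h = 12,
                         edge_boost = 1.6, edge_boost_min = 45,
                         seed_offset = 0L) {
  # offset_mean is evening-anchored: hours >= 24 mean "after midnight", so a
  # night block never collides with the previous night's sleep window
  stopifnot(nights >= 5, interval_min > 0, arousal_rate >= 0,
            offset_mean >= 12, offset_mean < 30)
  structure(as.list(environment()), class = "group_params")
}

#' Generate one synthetic participant
#'
#' Draws nightly rest windows with jitter around the group means, fills sleep
#' epochs with near-zero counts plus Poisson-placed arousal bouts of elevated
#' counts, and fills wake epochs with gamma-distributed counts modulated by a
#' smooth diurnal envelope peaking near the target acrophase and an hourly
#' behavioural factor. The diary records the drawn bed and wake times exactly
#' (diary noise defaults to zero so scoring error is attributable to the
#' scorer). Output is bit-identical for identical `(params, seed)`.
#'
#' @param params a [group_params()].
#' @param seed integer seed.
#' @param participant_id identifier.
#' @param start_date calendar date of the first recording day; by default a
#'   weekday drawn within the week so cohorts vary in full weekend days.
#' @return list: `series` ([epoch_series()]), `diary` (`diary_record`),
#'   `truth` (list with per-night bed/wake/offset/onset times, true arousal
#'   minutes, and the drawn participant-level parameters).
#' @export
generate_participant <- function(params, seed = 1L, participant_id = "sim1",
                                 start_date = NULL) {
  stopifnot(inherits(params, "group_params"))
  set.seed(seed)
  p <- params
  if (is.null(start_date))
    start_date <- as.Date("2024-03-04") + sample.int(7L, 1L) - 1L
  start_date <- as.Date(start_date)

  # participant-level means
  off_p <- stats::rnorm(1, p$offset_mean, p$offset_sd_between)
  int_p <- stats::rnorm(1, p$interval_min, p$interval_sd_between)

  nights <- p$nights
  off_i <- off_p + stats::rnorm(nights, 0, p$offset_sd_night)
  int_i <- pmax(240, int_p + stats::rnorm(nights, 0, p$interval_sd_night))
  sj <- p$schedule_jitter_min
  wind_i <- pmax(0, p$wind_down_min + stats::rnorm(nights, 0, sj))
  lie_i <- pmax(0, p$lie_in_min + stats::rnorm(nights, 0, sj))
  lat_i <- pmax(0, p$latency_min + stats::rnorm(nights, 0, sj / 2))

  # absolute seconds from midnight of recording day 1
  wind_start <- ((seq_len(nights) - 1) * 86400) + off_i * 3600
  bed <- wind_start + wind_i * 60
  settle_end <- bed + lat_i * 60
  wake <- bed + int_i * 60
  lie_end <- wake + lie_i * 60
  if (any(wake - settle_end <= 0))
    stop("parameters make the sleep window non-positive", call. = FALSE)

  el <- 30
  rec_start <- 15 * 3600                        # day 1, 15:00
  rec_end <- nights * 86400 + 12 * 3600         # last morning, 12:00
  n_ep <- as.integer((rec_end - rec_start) / el)
  t0 <- rec_start + (seq_len(n_ep) - 1L) * el   # epoch start seconds
  t_mid <- t0 + el / 2

  state <- rep.int(1L, n_ep)                    # 1 day,2 quiet,3 settle,4 sleep,5 bout
  mark <- function(state, a, b, code) {
    i0 <- pmax(1L, as.integer(ceiling((a - rec_start) / el)) + 1L)
    i1 <- pmin(n_ep, as.integer(ceiling((b - rec_start) / el)))
    for (k in seq_along(i0)) if (i1[k] >= i0[k]) state[i0[k]:i1[k]] <- code
    state
  }
  state <- mark(state, wind_start, bed, 2L)
  state <- mark(state, bed, settle_end, 3L)
  state <- mark(state, settle_end, wake, 4L)
  state <- mark(state, wake, lie_end, 2L)

  # arousal bouts inside the sleep window (15-min guard at both ends)
  arousal_min <- numeric(nights)
  for (k in seq_len(nights)) {
    lo <- settle_end[k] + 15 * 60
    hi <- wake[k] - 15 * 60
    if (hi <= lo || p$arousal_rate <= 0) next
    nb <- stats::rpois(1, p$arousal_rate)
    if (nb == 0) next
    starts <- sort(stats::runif(nb, lo, hi))
    durs <- rgamma_mean(nb, p$arousal_dur_min, shape = 2) * 60
    ends <- pmin(starts + durs, hi)
    state <- mark(state, starts, ends, 5L)
  }
  # true arousal minutes per night from the realized state vector
  for (k in seq_len(nights)) {
    sel <- t_mid >= settle_end[k] & t_mid < wake[k]
    arousal_min[k] <- sum(state[sel] == 5L) * el / 60
  }

  # daytime mean: diurnal envelope x ultradian modulation x per-hour
  # behavioural factor (AR(1) in log across consecutive hours)
  clock_h <- (t_mid / 3600) %% 24
  env <- pmax(0.15, 1 + p$env_amp * cos(2 * pi * (clock_h - p$acrophase_h) / 24))
  # ultradian routine phase-locked to clock time within a participant (meals,
  # school/work schedule), so it contributes to the repeatable daily profile
  # (leaves IS intact) while diluting the 24-h fundamental's share of power
  ult_phase <- stats::runif(1, 0, p$ultradian_period_h)
  ult <- pmax(0.2, 1 + p$ultradian_amp *
                cos(2 * pi * (t_mid / 3600 - ult_phase) /
                      p$ultradian_period_h))
  hour_key <- (t_mid %/% 3600) + 1              # absolute hour index
  n_hours <- max(hour_key)
  hfac <- if (p$hour_sd > 0) {
    phi <- p$hour_ar
    innov <- stats::rnorm(n_hours, 0, p$hour_sd * sqrt(1 - phi^2))
    lg <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                   init = stats::rnorm(1, 0, p$hour_sd)))
    exp(lg - p$hour_sd^2 / 2)
  } else rep(1, n_hours)

  # transition routines: elevated, reliable activity just after getting up
  # and just before winding down (real rest-activity transitions are sharp)
  boost <- rep(1, n_ep)
  if (p$edge_boost > 1 && p$edge_boost_min > 0) {
    eb <- p$edge_boost_min * 60
    for (k in seq_len(nights)) {
      sel <- t_mid >= wind_start[k] - eb & t_mid < wind_start[k] & state == 1L
      boost[sel] <- p$edge_boost
    }
    for (k in seq_len(nights)) {
      sel <- t_mid >= lie_end[k] & t_mid < lie_end[k] + eb & state == 1L
      boost[sel] <- p$edge_boost
    }
  }

  act <- numeric(n_ep)
  i_day <- state == 1L
  hf <- hfac[hour_key[i_day]]
  hf[boost[i_day] > 1] <- pmax(hf[boost[i_day] > 1], 1)  # routines override lulls
  act[i_day] <- rgamma_mean(sum(i_day), 1, p$day_shape) *
    p$day_mean * env[i_day] * ult[i_day] * hf * boost[i_day]
  i_quiet <- state == 2L
  act[i_quiet] <- rgamma_mean(sum(i_quiet), p$quiet_mean, 1)
  i_settle <- state == 3L
  act[i_settle] <- rgamma_mean(sum(i_settle), p$settle_mean, 1.5)
  i_sleep <- state == 4L
  act[i_sleep] <- stats::rpois(sum(i_sleep), p$sleep_lambda)
  i_bout <- state == 5L
  act[i_bout] <- rgamma_mean(sum(i_bout), p$arousal_amp, 1.5)
  act <- round(act)

  start_posix <- as.POSIXct(paste(start_date), tz = "UTC") + rec_start
  series <- epoch_series(act, start_posix, epoch_length = el,
                         participant_id = participant_id)
  base_mid <- as.POSIXct(paste(start_date), tz = "UTC")
  diary <- diary_record(
    participant_id = participant_id,
    date = start_date + (seq_len(nights) - 1L),
    bedtime = format(base_mid + bed, "%H:%M:%S"),
    waketime = format(base_mid + wake, "%H:%M:%S")
  )
  # diary_record re-derives wake as bed's clock + wrap; rebuild exact POSIXct
  diary$bedtime <- base_mid + bed
  diary$waketime <- base_mid + wake

  truth <- list(
    participant_id = participant_id,
    offset_hours = off_i %% 24,                 # template-target offsets
    onset_hours = (lie_end / 3600) %% 24,       # template-target onsets
    bed_sec = bed, wake_sec = wake,
    interval_min = int_i, latency_min = lat_i,
    arousal_min = arousal_min,
    participant_offset = off_p %% 24,
    start_date = start_date, seed = seed
  )
  list(series = series, diary = diary, truth = truth)
}

# Planted regression structure linking interdaily stability and age to the
# cognitive outcomes; signs reproduce the reference study's fitted models
# (positive IS and age slopes for reaction time; negative IS slopes for
# verbal and scene recall; positive age slope for object-context binding).
# `scale` names the measurement scale the linear model lives on after the
# pipeline's transform ("log"/"sqrt" outcomes are generated by inverting it).
#' Default cognitive outcome linkage
#'
#' @return tibble: `outcome`, `scale`, `b0`, `b_is`, `b_age`, `sd`.
#' @export
default_cognitive_betas <- function() {
  tibble::tribble(
    ~outcome,          ~scale,  ~b0,  ~b_is, ~b_age, ~sd,
    "reaction_time",   "none",  0.8,   3.2,   0.05,  0.38,
    "verbal_recall",   "log",   3.2,  -2.0,   0.00,  0.45,
    "scene_recall",    "log",   2.9,  -1.6,   0.00,  0.40,
    "object_binding",  "log",   1.8,   0.0,   0.06,  0.45,
    "visual_recall",   "sqrt",  2.6,   0.0,   0.00,  0.50,
    "spatial_recall",  "none", 12.0,   0.0,   0.00,  4.00,
    "kbit_verbal",     "none", 30.0,   0.0,   0.00, 10.00,
    "brief_gec",       "none", 60.0,   0.0,   0.00,  8.00
  )
}

#' Generate a full synthetic cohort
#'
#' Generates every participant of every group, computes each participant's
#' interdaily stability from the generated data, and links the cognitive
#' outcomes to it through the planted coefficients
#' `y = b0 + b_is * IS + b_age * age + eps` (on the outcome's model scale;
#' log- and sqrt-scale outcomes are back-transformed so the pipeline's
#' transform recovers the linear model). Optionally writes the same CSV
#' dialects the io module reads.
#'
#' @param presets named list of [group_params()] (default [reference_presets()]).
#' @param betas cognitive linkage tibble (default [default_cognitive_betas()];
#'   set the `b_*` columns to zero for null cohorts).
#' @param seed master seed; per-participant seeds derive from it.
#' @param out_dir optional directory: writes `epochs_<id>.csv` per participant,
#'   `diary.csv`, `cohort.csv` and `ground_truth.json` (requires jsonlite).
#' @return list: `participants` (list of `generate_participant()` outputs),
#'   `info` (cohort tibble: id, group, age_group, age, gender, weekend_days,
#'   cognitive outcomes, `is_true`), `betas`, `seed`.
#' @export
generate_cohort <- function(presets = reference_presets(),
                            betas = default_cognitive_betas(),
                            seed = 1L, out_dir = NULL) {
  stopifnot(length(presets) >= 1L)
  participants <- list()
  info_rows <- list()
  g_idx <- 0L
  for (gname in names(presets)) {
    g_idx <- g_idx + 1L
    p <- presets[[gname]]
    for (j in seq_len(p$n)) {
      pid <- sprintf("%s_%02d", gname, j)
      pseed <- (abs(seed) * 131L + g_idx * 1009L + j * 7L +
                  p$seed_offset) %% 2147483647L
      sim <- generate_participant(p, seed = pseed, participant_id = pid)
      set.seed(pseed + 1L)
      age <- stats::runif(1, p$age_range[1], p$age_range[2])
      gender <- sample(c("F", "M"), 1L)
      dm <- trim_to_full_days(sim$series, bins_per_day = 24)
      is_true <- interdaily_stability(dm)
      dates <- attr(dm, "day_dates")
      weekend_days <- sum(format(dates, "%u") %in% c("6", "7"))
      row <- tibble::tibble(participant_id = pid, group = p$group,
                            age_group = p$age_group, age = age,
                            gender = gender, weekend_days = weekend_days,
                            is_true = is_true,
                            ef_accuracy = stats::runif(1, 0.7, 1.0))
      for (i in seq_len(nrow(betas))) {
        b <- betas[i, ]
        lin <- b$b0 + b$b_is * is_true + b$b_age * age +
          stats::rnorm(1, 0, b$sd)
        row[[b$outcome]] <- switch(b$scale,
                                   none = lin,
                                   log = exp(lin),
                                   sqrt = pmax(0, lin)^2)
      }
      participants[[pid]] <- sim
      info_rows[[pid]] <- row
    }
  }
  info <- dplyr::bind_rows(info_rows)
  out <- list(participants = participants, info = info, betas = betas,
              seed = seed)
  if (!is.null(out_dir)) write_cohort_csvs(out, out_dir)
  out
}

#' Write a generated cohort to disk
#'
#' @param cohort output of [generate_cohort()].
#' @param out_dir target directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_cohort_csvs <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (pid in names(cohort$participants)) {
    write_epoch_csv(cohort$participants[[pid]]$series,
                    file.path(out_dir, paste0("epochs_", pid, ".csv")))
  }
  diaries <- dplyr::bind_rows(lapply(cohort$participants, `[[`, "diary"))
  write_diary_csv(diaries, file.path(out_dir, "diary.csv"))
  readr::write_csv(cohort$info, file.path(out_dir, "cohort.csv"),
                   progress = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truths <- lapply(cohort$participants, `[[`, "truth")
    jsonlite::write_json(truths, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(out_dir)
}
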