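#' Epoch-level actigraphy series
#'
#' The raw substrate of every analysis in the package: a uniformly sampled,
#' clock-anchored sequence of non-negative activity counts (one per epoch,
#' 30 s by default), optionally with ambient light (lux) and an off-wrist mask.
#' Timestamps are treated as naive local clock time: no time-zone or
#' daylight-saving conversion is ever applied, matching how wrist actigraphs
#' export data.
#'
#' @param activity numeric vector of non-negative, finite counts, one per epoch.
#' @param start POSIXct (or parseable string) local date-time of the first epoch.
#' @param epoch_length epoch duration in seconds; must divide 86400 evenly.
#' @param participant_id opaque participant identifier.
#' @param light optional lux vector, same length as `activity`.
#' @param off_wrist optional logical vector, same length as `activity`.
#' @return an object of class `epoch_series`.
#' @export
epoch_series <- function(activity, start, epoch_length = 30,
                         participant_id = "participant", light = NULL,
                         off_wrist = NULL) {
  if (is.character(start)) start <- as.POSIXct(start, tz = "UTC")
  stopifnot(inherits(start, "POSIXct"), length(start) == 1L)
  activity <- as.numeric(activity)
  if (length(activity) < 1L)
    stop("activity must contain at least one epoch", call. = FALSE)
  if (anyNA(activity) || any(!is.finite(activity)))
    stop("activity contains missing or non-finite values", call. = FALSE)
  if (any(activity < 0))
    stop("activity counts must be non-negative", call. = FALSE)
  epoch_length <- as.numeric(epoch_length)
  if (epoch_length <= 0 || 86400 %% epoch_length != 0)
    stop("epoch_length must be a positive divisor of 86400 seconds", call. = FALSE)
  if (!is.null(light)) {
    light <- as.numeric(light)
    if (length(light) != length(activity))
      stop("light must have the same length as activity", call. = FALSE)
    if (any(light < 0, na.rm = TRUE))
      stop("light values must be non-negative", call. = FALSE)
  }
  if (!is.null(off_wrist)) {
    off_wrist <- as.logical(off_wrist)
    if (length(off_wrist) != length(activity))
      stop("off_wrist must have the same length as activity", call. = FALSE)
  }
  structure(
    list(participant_id = as.character(participant_id),
         start = start,
         epoch_length = epoch_length,
         activity = activity,
         light = light,
         off_wrist = off_wrist),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  days <- length(x$activity) * x$epoch_length / 86400
  cat(sprintf("<epoch_series> %s: %d epochs of %gs (%.2f days) from %s\n",
              x$participant_id, length(x$activity), x$epoch_length,
              days, format(x$start, "%Y-%m-%d %H:%M:%S")))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$activity)

# POSIXct timestamp of every epoch start.
epoch_times <- function(series) {
  series$start + (seq_along(series$activity) - 1L) * series$epoch_length
}

#' Read an epoch-level actigraphy CSV
#'
#' Expects one row per epoch with a `timestamp` column (ISO-8601 local
#' date-time) and an `activity` column of counts; optional `lux` and
#' `off_wrist` (0/1) columns. Vendor-export dialects are accommodated through
#' `col_map`, which renames columns before validation. Epoch length is
#' inferred from consecutive timestamps and checked to be constant: a missing
#' or duplicated epoch row is reported as a format error naming the first
#' irregular timestamp pair.
#'
#' @param path CSV file path.
#' @param col_map named list mapping the canonical names `timestamp`,
#'   `activity`, `lux`, `off_wrist` to the column names found in the file.
#' @param participant_id identifier; defaults to the file name without extension.
#' @param delim field delimiter.
#' @return an [epoch_series()].
#' @export
read_epoch_csv <- function(path, col_map = list(), participant_id = NULL,
                           delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(.default = readr::col_guess()))
  canon <- list(timestamp = "timestamp", activity = "activity",
                lux = "lux", off_wrist = "off_wrist")
  canon[names(col_map)] <- col_map
  for (need in c("timestamp", "activity")) {
    if (!canon[[need]] %in% names(df))
      stop("missing required column '", canon[[need]], "' in ", path, call. = FALSE)
  }
  ts <- df[[canon$timestamp]]
  if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(as.character(ts), tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamps in ", path, call. = FALSE)
  d <- diff(as.numeric(ts))
  if (length(d)) {
    bad <- which(abs(d - d[1L]) > 1e-6)
    if (length(bad)) {
      i <- bad[1L]
      stop(sprintf(
        "non-uniform epoch spacing between rows %d and %d (%s -> %s): expected %gs, found %gs",
        i, i + 1L, format(ts[i]), format(ts[i + 1L]), d[1L], d[i]), call. = FALSE)
    }
  }
  act <- as.numeric(df[[canon$activity]])
  if (any(act < 0, na.rm = TRUE))
    stop("negative activity counts in ", path, call. = FALSE)
  epoch_series(
    activity = act,
    start = ts[1L],
    epoch_length = if (length(d)) d[1L] else 30,
    participant_id = participant_id %||% sub("\\.[^.]+$", "", basename(path)),
    light = if (canon$lux %in% names(df)) as.numeric(df[[canon$lux]]) else NULL,
    off_wrist = if (canon$off_wrist %in% names(df))
      as.logical(as.integer(df[[canon$off_wrist]])) else NULL
  )
}

#' Write an epoch series to CSV
#'
#' Inverse of [read_epoch_csv()]; the round trip reproduces activity values
#' bit-exactly.
#'
#' @param series an [epoch_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path) {
  df <- tibble::tibble(
    timestamp = format(epoch_times(series), "%Y-%m-%dT%H:%M:%S"),
    activity = series$activity
  )
  if (!is.null(series$light)) df$lux <- series$light
  if (!is.null(series$off_wrist)) df$off_wrist <- as.integer(series$off_wrist)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a sleep-diary CSV
#'
#' One row per night: `participant_id,date,bedtime,waketime,n_wakings,nap_intervals`.
#' `date` is the evening the night begins; `bedtime`/`waketime` are clock times
#' (`HH:MM` or `HH:MM:SS`). A wake time at or before the bedtime is interpreted
#' as falling after midnight (midnight-wrap correction). `nap_intervals` is an
#' optional `;`-separated list of `HH:MM-HH:MM` daytime intervals.
#'
#' @param path CSV file path.
#' @return a tibble of class `diary_record` with POSIXct `bedtime`/`waketime`.
#' @export
read_diary_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  for (need in c("participant_id", "date", "bedtime", "waketime")) {
    if (!need %in% names(df)) stop("diary is missing column '", need, "'", call. = FALSE)
  }
  diary_record(
    participant_id = df$participant_id,
    date = as.Date(df$date),
    bedtime = df$bedtime,
    waketime = df$waketime,
    n_wakings = if ("n_wakings" %in% names(df)) as.integer(df$n_wakings) else NA_integer_,
    nap_intervals = if ("nap_intervals" %in% names(df)) df$nap_intervals else NA_character_
  )
}

#' Construct a diary record
#'
#' @param participant_id participant identifier (recycled).
#' @param date Date of the evening each night begins.
#' @param bedtime,waketime clock times (`HH:MM[:SS]` strings or hours); a wake
#'   time not after the bedtime wraps to the next calendar day.
#' @param n_wakings optional reported out-of-bed night wakings.
#' @param nap_intervals optional `;`-separated `HH:MM-HH:MM` daytime nap list.
#' @return tibble of class `diary_record` with one row per night and POSIXct
#'   `bedtime`/`waketime` columns.
#' @export
diary_record <- function(participant_id, date, bedtime, waketime,
                         n_wakings = NA_integer_, nap_intervals = NA_character_) {
  date <- as.Date(date)
  bed_s <- parse_clock(bedtime)
  wake_s <- parse_clock(waketime)
  bed <- as.POSIXct(paste(date), tz = "UTC") + bed_s
  wake <- as.POSIXct(paste(date), tz = "UTC") + wake_s +
    ifelse(wake_s <= bed_s, 86400, 0)
  out <- tibble::tibble(
    participant_id = as.character(participant_id),
    date = date, bedtime = bed, waketime = wake,
    n_wakings = n_wakings, nap_intervals = nap_intervals
  )
  if (any(out$waketime <= out$bedtime))
    stop("diary wake time does not follow bedtime after midnight-wrap correction",
         call. = FALSE)
  class(out) <- c("diary_record", class(out))
  out
}

#' Write a diary record to CSV
#'
#' @param diary a `diary_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diary_csv <- function(diary, path) {
  # the written date is the bedtime's own calendar date (not the evening the
  # night began), so after-midnight bedtimes round-trip exactly
  df <- tibble::tibble(
    participant_id = diary$participant_id,
    date = format(as.Date(diary$bedtime)),
    bedtime = format(diary$bedtime, "%H:%M:%S"),
    waketime = format(diary$waketime, "%H:%M:%S"),
    n_wakings = diary$n_wakings,
    nap_intervals = diary$nap_intervals
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
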