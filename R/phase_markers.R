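# Phase markers: template-matching activity onsets/offsets and 24-h cosinor.

# Binarize a day matrix: a bin is "active" (+1) iff its count exceeds the
# participant's median bin count, else -1. Median is scale-free, so the
# markers are invariant to count units. Degenerate tie case: when the median
# equals the series maximum (two-level data with an active majority), bins at
# the median count as active, so a square-wave day still binarizes to its
# wake span.
binarize_day_matrix <- function(dm) {
  v <- as.numeric(t(unclass(dm)))           # flattened, day-major
  thr <- stats::median(v)
  s <- v > thr
  if (!any(s)) s <- v >= thr & v > min(v)
  ifelse(s, 1, -1)
}

# Shared engine: step-template correlation at every bin boundary.
# For an onset template (5 h low then 5 h high) the score at boundary j is
# sum(s[j .. j+H-1]) - sum(s[j-H .. j-1]) on the +/-1 series s, with circular
# wrap over the whole recording so boundaries near the day edges see the
# adjacent days. Offsets use the mirrored template (= negated score).
template_match_engine <- function(dm, template_hours = 5, sign = 1) {
  stopifnot(inherits(dm, "day_matrix"))
  bs <- attr(dm, "bin_seconds")
  if (bs > 3600) stop("template matching needs bins of 1 h or finer", call. = FALSE)
  B <- ncol(dm); D <- nrow(dm)
  H <- as.integer(round(template_hours * 3600 / bs))
  s <- binarize_day_matrix(dm)
  n <- length(s)
  if (n < 2L * H) stop("recording shorter than the template", call. = FALSE)
  cs <- cumsum(c(s, s, s))                  # circular padding
  idx <- seq_len(n)
  hi <- (cs[idx + n + H - 1L] - cs[idx + n - 1L])          # s[j .. j+H-1]
  lo <- (cs[idx + n - 1L] - cs[idx + n - H - 1L])          # s[j-H .. j-1]
  score <- sign * (hi - lo)
  edge <- bin_edge_hours(dm)
  per_day <- lapply(seq_len(D), function(d) {
    j <- (d - 1L) * B + seq_len(B)
    day_vals <- unclass(dm)[d, ]
    if (stats::var(day_vals) == 0) {
      return(tibble::tibble(day = d, hours = NA_real_, score = NA_real_,
                            flagged = TRUE))
    }
    sc <- score[j]
    best <- which.max(sc)                   # earliest maximal boundary
    tibble::tibble(day = d, hours = edge[best], score = sc[best],
                   flagged = FALSE)
  })
  dplyr::bind_rows(per_day)
}

#' Template-matched daily activity onsets
#'
#' For each complete day, the activity onset is the bin boundary maximizing
#' the correlation of the binarized activity with a step template of 5 h
#' inactivity followed by 5 h activity, searched over every boundary with wrap
#' into adjacent days. Ties resolve to the earliest maximal boundary. Constant
#' days are flagged and excluded from the average. The participant-level value
#' is the circular mean of the per-day onsets.
#'
#' @param dm a [day_matrix] at hourly or finer bins.
#' @param template_hours half-template duration in hours (default 5).
#' @return list: `per_day` tibble (`day`, `onset_hours`, `flagged`),
#'   `mean_hours` circular mean onset.
#' @export
template_match_onsets <- function(dm, template_hours = 5) {
  res <- template_match_engine(dm, template_hours, sign = 1)
  per_day <- tibble::tibble(day = res$day, onset_hours = res$hours,
                            flagged = res$flagged)
  list(per_day = per_day,
       mean_hours = circular_mean_hours(per_day$onset_hours))
}

#' Template-matched daily activity offsets
#'
#' Mirror of [template_match_onsets()]: a 5-h period of high activity followed
#' by 5 h of relative inactivity marks the offset (settling into the nightly
#' rest period).
#'
#' @inheritParams template_match_onsets
#' @return list: `per_day` tibble (`day`, `offset_hours`, `flagged`),
#'   `mean_hours` circular mean offset.
#' @export
template_match_offsets <- function(dm, template_hours = 5) {
  res <- template_match_engine(dm, template_hours, sign = -1)
  per_day <- tibble::tibble(day = res$day, offset_hours = res$hours,
                            flagged = res$flagged)
  list(per_day = per_day,
       mean_hours = circular_mean_hours(per_day$offset_hours))
}

#' Single-component 24-h cosinor fit
#'
#' Fits `M + A * cos(2*pi*(t - phi)/24)` to each day's activity by least
#' squares in the linear sine/cosine parameterization; the acrophase `phi` is
#' the clock time of the fitted peak. Participant-level values are the
#' arithmetic means of MESOR and amplitude and the circular mean of the
#' acrophase. A zero-variance day yields amplitude 0 with the acrophase
#' flagged as undefined.
#'
#' @param dm a [day_matrix] (any bin width).
#' @param period fitted period in hours (default 24).
#' @return list of class `cosinor_fit`: `per_day` tibble (`day`, `mesor`,
#'   `amplitude`, `acrophase_hours`, `flagged`), and participant-level
#'   `mesor`, `amplitude`, `acrophase_hours`.
#' @export
cosinor_fit <- function(dm, period = 24) {
  stopifnot(inherits(dm, "day_matrix"))
  t_h <- bin_centre_hours(dm)
  w <- 2 * pi / period
  X <- cbind(1, cos(w * t_h), sin(w * t_h))
  per_day <- lapply(seq_len(nrow(dm)), function(d) {
    y <- unclass(dm)[d, ]
    if (stats::var(y) == 0) {
      return(tibble::tibble(day = d, mesor = mean(y), amplitude = 0,
                            acrophase_hours = NA_real_, flagged = TRUE))
    }
    beta <- stats::lm.fit(X, y)$coefficients
    amp <- sqrt(beta[2]^2 + beta[3]^2)
    phi <- (atan2(beta[3], beta[2]) / w) %% period
    tibble::tibble(day = d, mesor = beta[1], amplitude = amp,
                   acrophase_hours = phi, flagged = FALSE)
  })
  per_day <- dplyr::bind_rows(per_day)
  ok <- per_day[!per_day$flagged, , drop = FALSE]
  structure(list(per_day = per_day,
                 mesor = mean(per_day$mesor),
                 amplitude = mean(per_day$amplitude),
                 acrophase_hours = circular_mean_hours(ok$acrophase_hours)),
            class = "cosinor_fit")
}
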