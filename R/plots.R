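# Figures: double-plotted actogram and average 24-h activity profile.

#' Double-plotted actogram
#'
#' One row per day, each row showing 48 h (the day and the following day), the
#' standard layout for eyeballing phase drift. Optional acrophase markers are
#' drawn as dots at the fitted daily peak time.
#'
#' @param dm a [day_matrix].
#' @param acrophase optional per-day acrophase hours (e.g. from
#'   [cosinor_fit()]`$per_day$acrophase_hours`).
#' @param double double-plot (48-h rows) or single-plot (24-h rows).
#' @return a ggplot object.
#' @export
plot_actogram <- function(dm, acrophase = NULL, double = TRUE) {
  m <- unclass(dm)
  D <- nrow(m); B <- ncol(m)
  bin_h <- attr(dm, "bin_seconds") / 3600
  df <- tidyr::expand_grid(day = seq_len(D), bin = seq_len(B))
  df$activity <- as.numeric(t(m))
  df$hour <- (df$bin - 0.5) * bin_h
  if (double && D > 1L) {
    nxt <- df[df$day > 1L, ]
    nxt$day <- nxt$day - 1L
    nxt$hour <- nxt$hour + 24
    df <- rbind(df, nxt)
  }
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$hour,
                                        y = .data$activity / max(.data$activity))) +
    ggplot2::geom_col(width = bin_h, fill = "grey20") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$day), switch = "y") +
    ggplot2::scale_x_continuous(breaks = seq(0, if (double) 48 else 24, 6),
                                expand = c(0, 0)) +
    ggplot2::labs(x = "clock time (h)", y = NULL,
                  title = attr(dm, "participant_id")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank(),
                   strip.text.y.left = ggplot2::element_text(angle = 0))
  if (!is.null(acrophase)) {
    ac <- tibble::tibble(day = seq_along(acrophase), hour = acrophase)
    ac <- ac[!is.na(ac$hour), ]
    g <- g + ggplot2::geom_point(data = ac,
                                 ggplot2::aes(x = .data$hour, y = 1.05),
                                 colour = "red", size = 1.5)
  }
  g
}

#' Average 24-h activity profile
#'
#' Mean activity per bin across all retained days, the standard companion
#' figure to the actogram.
#'
#' @param dm a [day_matrix].
#' @return a ggplot object.
#' @export
plot_daily_profile <- function(dm) {
  prof <- colMeans(unclass(dm))
  bin_h <- attr(dm, "bin_seconds") / 3600
  df <- tibble::tibble(hour = (seq_along(prof) - 0.5) * bin_h, activity = prof)
  ggplot2::ggplot(df, ggplot2::aes(.data$hour, .data$activity)) +
    ggplot2::geom_line(colour = "grey20") +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6), expand = c(0, 0)) +
    ggplot2::labs(x = "clock time (h)", y = "mean counts per epoch",
                  title = attr(dm, "participant_id")) +
    ggplot2::theme_minimal()
}
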