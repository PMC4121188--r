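#' Plot a simulation run
#'
#' The default panel shows total chromosome-containing length over time on
#' a log2 axis (bulk exponential growth); `what = "lengths"` shows the
#' final cell-length distribution and `what = "blocked"` the blocked-site
#' trajectory.
#'
#' @param object A `mindivsim_run`.
#' @param what `"growth"`, `"lengths"` or `"blocked"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mindivsim_run <- function(object, what = c("growth", "lengths", "blocked"),
                                   ...) {
  what <- match.arg(what)
  if (what == "growth") {
    ggplot2::ggplot(object$series,
                    ggplot2::aes(x = .data$t_min, y = .data$total_length_nm)) +
      ggplot2::geom_line() +
      ggplot2::scale_y_continuous(trans = "log2") +
      ggplot2::labs(x = "time (min)", y = "total length (nm, log2)",
                    title = "Bulk culture growth")
  } else if (what == "lengths") {
    plot_length_distribution(final_snapshot(object))
  } else {
    ggplot2::ggplot(object$series,
                    ggplot2::aes(x = .data$t_min,
                                 y = .data$n_sites_blocked / .data$n_cells)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (min)", y = "blocked sites per cell",
                    title = "Segregation-defect blocking level")
  }
}

final_snapshot <- function(run) {
  dplyr::filter(run$snapshots, .data$t_min == max(.data$t_min))
}

#' Cell-length distribution plot
#'
#' Histogram of chromosome-containing cell lengths (minicells excluded),
#' in micrometres.
#'
#' @param snapshot A snapshot tibble.
#' @param binwidth_um Bin width in micrometres.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(snapshot, binwidth_um = 0.5) {
  mini <- if ("is_minicell" %in% names(snapshot)) snapshot$is_minicell else FALSE
  d <- snapshot[!mini, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length_nm / 1000)) +
    ggplot2::geom_histogram(binwidth = binwidth_um, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "cell length (µm)", y = "cells",
                  title = "Cell length distribution")
}

#' Division waiting-time distribution plot
#'
#' @param tracking A tracking table.
#' @param binwidth Bin width, minutes.
#' @return A ggplot object faceted by site class (polar vs non-polar).
#' @export
plot_waiting_times <- function(tracking, binwidth = 5) {
  d <- waiting_time_distribution(tracking, binwidth = binwidth)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::facet_wrap(~site_class, scales = "free_y") +
    ggplot2::labs(x = "division waiting time (min)", y = "events",
                  title = "Division waiting times")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
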