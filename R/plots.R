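# ggplot2 figures for the standard result types.

#' Raster plot of a well's spike trains
#'
#' One row per electrode, a tick per spike, with optional single-channel
#' burst segments and shaded network-burst events overlaid.
#'
#' @param spikes Spike tibble (`electrode_id`, `spike_time_s`).
#' @param bursts Optional burst tibble from [detect_bursts()].
#' @param network_bursts Optional event tibble from
#'   [detect_network_bursts()].
#' @param window Optional `c(start, end)` seconds to restrict the x-axis.
#' @return A ggplot object.
#' @export
plot_raster <- function(spikes, bursts = NULL, network_bursts = NULL,
                        window = NULL) {
  stopifnot(is.data.frame(spikes))
  p <- ggplot2::ggplot(spikes,
                       ggplot2::aes(x = .data$spike_time_s,
                                    y = factor(.data$electrode_id)))
  if (!is.null(network_bursts) && nrow(network_bursts)) {
    p <- p + ggplot2::geom_rect(
      data = network_bursts,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s),
      ymin = -Inf, ymax = Inf, fill = "indianred", alpha = 0.25,
      inherit.aes = FALSE
    )
  }
  p <- p + ggplot2::geom_point(shape = "|", size = 2)
  if (!is.null(bursts) && nrow(bursts)) {
    p <- p + ggplot2::geom_segment(
      data = bursts,
      ggplot2::aes(x = .data$start_s, xend = .data$end_s,
                   y = factor(.data$electrode_id),
                   yend = factor(.data$electrode_id)),
      linewidth = 2, colour = "steelblue", alpha = 0.6,
      inherit.aes = FALSE
    )
  }
  if (!is.null(window)) p <- p + ggplot2::coord_cartesian(xlim = window)
  p + ggplot2::labs(x = "time (s)", y = "electrode") + ggplot2::theme_minimal()
}

#' Normalized metric time-course with mean ± SEM bands
#'
#' @param aggregates Output of [aggregate_condition()].
#' @param metric Which metric to draw (default `"nbr_norm"`).
#' @return A ggplot object.
#' @export
plot_timecourse <- function(aggregates, metric = "nbr_norm") {
  stopifnot(is.data.frame(aggregates))
  d <- dplyr::filter(aggregates, .data$metric == !!metric)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$timepoint_h, y = .data$mean,
                                  colour = .data$condition,
                                  fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "hours in hypoxia", y = paste(metric, "(baseline = 1)")) +
    ggplot2::theme_minimal()
}

#' Per-timepoint adjusted p-values of a condition comparison
#'
#' @param object A `mea_comparison` from [compare_conditions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mea_comparison <- function(object, ...) {
  d <- object$results
  ggplot2::ggplot(d, ggplot2::aes(x = .data$timepoint_h,
                                  y = -log10(.data$adjusted_p),
                                  colour = .data$comparison)) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "hours in hypoxia",
                  y = expression(-log[10] ~ "adjusted p (Bonferroni)")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
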