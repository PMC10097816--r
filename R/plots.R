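# ggplot2 views of the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.walkstress_segment_sweep <- function(object, feature_set = "all", ...) {
  df <- object[object$feature_set == feature_set, , drop = FALSE]
  long <- tidyr::pivot_longer(
    df, c("uar", "recall_stimuli", "recall_nonstimuli"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$segment_length_m,
                                     y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "POI segment length (m)", y = "recall / UAR",
      colour = NULL,
      title = sprintf("Segment-length sweep (%s features)", feature_set)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.walkstress_window_sweep <- function(object, ...) {
  ggplot2::ggplot(object$lme_grid,
                  ggplot2::aes(x = .data$window_length_s, y = .data$p.value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "window length (s)", y = "LME p-value",
                  title = "Stimulus-window length sweep") +
    ggplot2::theme_minimal()
}

#' Street-segment distress heat map
#'
#' Draws POI segments colored by an aggregate (default the mean normalized
#' skin conductance level) with reported stimulus locations overlaid - the
#' package's map-export view.
#'
#' @param segments POI segment tibble.
#' @param samples labeled segment samples.
#' @param reports optional report tibble to overlay.
#' @param fill name of the aggregate column to color by.
#' @return a ggplot object.
#' @export
plot_segment_map <- function(segments, samples, reports = NULL,
                             fill = "scl_mean") {
  df <- dplyr::inner_join(segments, samples, by = "segment_id")
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                   colour = .data[[fill]]),
      linewidth = 2
    ) +
    ggplot2::scale_colour_viridis_c(option = "plasma") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = fill,
                  title = "POI segments") +
    ggplot2::theme_minimal()
  if (!is.null(reports) && nrow(reports) > 0) {
    p <- p + ggplot2::geom_point(
      data = reports,
      ggplot2::aes(x = .data$x_m, y = .data$y_m),
      colour = "red", shape = 21, fill = NA, size = 2, stroke = 0.8
    )
  }
  p
}
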