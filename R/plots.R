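#' Raster plot of a spike-train set
#'
#' Electrode-by-time spike raster, the standard display for well-wide
#' synchrony: network bursts appear as vertical stripes.
#'
#' @param trains A `spike_trains` tibble.
#' @return A ggplot object.
#' @export
plot_raster <- function(trains) {
  ev <- raster_events(trains)
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$time_s,
                                   y = factor(.data$electrode))) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = "electrode") +
    ggplot2::theme_minimal()
}

#' Spike-amplitude heatmap on the electrode grid
#'
#' Mean absolute spike amplitude per electrode at its grid position;
#' electrodes without spikes are blank.
#'
#' @param trains A `spike_trains` tibble with amplitudes.
#' @return A ggplot object.
#' @export
plot_amplitude_heatmap <- function(trains) {
  hm <- amplitude_heatmap(trains)
  ggplot2::ggplot(hm, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$mean_abs_amplitude_uv)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "|amplitude| (uV)") +
    ggplot2::theme_minimal()
}

#' Plot a swim trajectory in its well
#'
#' @param object An `mea_trajectory` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mea_trajectory <- function(object, ...) {
  r <- attr(object, "arena_radius")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x_mm, y = .data$y_mm))
  if (is.finite(r)) {
    circle <- tibble(theta = seq(0, 2 * pi, length.out = 200))
    circle$x <- r * cos(circle$theta)
    circle$y <- r * sin(circle$theta)
    p <- p + ggplot2::geom_path(data = circle,
                                ggplot2::aes(x = .data$x, y = .data$y),
                                color = "grey60", inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_path(ggplot2::aes(color = .data$phase), linewidth = 0.3) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-bin behavioral metrics across dark/light cycles
#'
#' @param bins Per-bin table from [bin_by_phase()].
#' @param metric Column to plot (default `"velocity_mm_s"`).
#' @return A ggplot object.
#' @export
plot_phase_bins <- function(bins, metric = "velocity_mm_s") {
  stopifnot(metric %in% names(bins))
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data[[metric]],
                                     fill = .data$phase)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(dark = "grey30", light = "gold"),
                               na.value = "grey70") +
    ggplot2::labs(x = "2-min bin", y = metric) +
    ggplot2::theme_minimal()
}
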