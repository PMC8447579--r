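#' Diurnal percentile-box plot of field summaries
#'
#' Displays, per crop and overpass time, the median with the interquartile
#' box and the full range of a summarized variable — the diurnal "box plot"
#' view of the per-field statistics.
#'
#' @param summaries Output of [field_stats()].
#' @param variable Which variable to plot (one of the summarized names).
#' @return A ggplot object.
#' @export
plot_field_stats <- function(summaries, variable) {
  data <- dplyr::filter(summaries, .data$variable == !!variable)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$time, colour = .data$crop)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$p0, ymax = .data$p100),
                            linewidth = 0.3, alpha = 0.6,
                            position = ggplot2::position_dodge(width = 0.25)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(y = .data$p50, ymin = .data$p25, ymax = .data$p75),
      size = 0.3, linewidth = 0.9,
      position = ggplot2::position_dodge(width = 0.25)) +
    ggplot2::labs(x = "local time (h)", y = variable, colour = "crop") +
    ggplot2::theme_minimal()
}

#' Hysteresis loop plot
#'
#' Plots the chronologically connected efficiency-versus-driver trajectory
#' per crop; non-coinciding morning and afternoon branches show as an open
#' loop.
#'
#' @param object A `sif_hysteresis` tibble from [hysteresis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sif_hysteresis <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$driver_mean, y = .data$eps_mean,
                               colour = .data$crop, group = .data$crop)) +
    ggplot2::geom_path(arrow = grid::arrow(length = grid::unit(2, "mm"),
                                           type = "closed")) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$eps_mean - .data$eps_sd,
                   ymax = .data$eps_mean + .data$eps_sd),
      size = 0.2) +
    ggplot2::labs(x = "driver (mW m-2)", y = "emission efficiency (nm-1)",
                  colour = "crop") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sif_hysteresis
#' @param x A `sif_hysteresis` tibble.
#' @importFrom ggplot2 autoplot
#' @export
plot_hysteresis <- function(x, ...) autoplot.sif_hysteresis(x, ...)

#' Map plot of a per-pixel variable
#'
#' @param pixels A pixel table with `x`, `y` and the variable column.
#' @param variable Column name to map.
#' @return A ggplot object (reversed y axis, north up).
#' @export
plot_map <- function(pixels, variable) {
  ggplot2::ggplot(pixels,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data[[variable]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(fill = variable) +
    ggplot2::theme_minimal()
}

#' Canopy-leaf correlation plot
#'
#' Field-level canopy-versus-leaf SIF correlation coefficients over the
#' diurnal course, coloured by crop.
#'
#' @param correlations Output of [canopy_leaf_correlation()].
#' @return A ggplot object.
#' @export
plot_correlations <- function(correlations) {
  ggplot2::ggplot(dplyr::filter(correlations, !is.na(.data$r)),
                  ggplot2::aes(x = .data$time, y = .data$r,
                               colour = .data$crop)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.2)) +
    ggplot2::ylim(NA, 1) +
    ggplot2::labs(x = "local time (h)", y = "Pearson r (canopy vs leaf)") +
    ggplot2::theme_minimal()
}
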