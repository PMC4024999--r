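# ggplot2 convenience layers for the main result types.

#' Plot a detection curve
#'
#' Cumulative percentage of respondents detecting odor at or within each
#' distance, walking toward the source.
#'
#' @param object A [detection_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.detection_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance,
                                       y = 100 * .data$frac_within)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Distance from source (m)",
                  y = "Detected at or within distance (%)")
}

#' Plot period-mean concentrations of a forward run
#'
#' @param object A `plume_run` from [run_forward()].
#' @param ... Unused.
#' @return A ggplot of period-mean concentration per receptor, filled by
#'   source.
#' @export
autoplot.plume_run <- function(object, ...) {
  ggplot2::ggplot(object$period_mean,
                  ggplot2::aes(x = .data$receptor, y = .data$mean_conc,
                               fill = .data$source)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Receptor", y = "Period-mean concentration",
                  fill = "Source")
}

#' Plot an hourly emission or diurnal index series
#'
#' @param series Tibble with `time` (or `hour`) and `rate` (or `index`).
#' @return A ggplot line chart.
#' @export
plot_emission_series <- function(series) {
  xvar <- if ("time" %in% names(series)) "time" else "hour"
  yvar <- if ("rate" %in% names(series)) "rate" else "index"
  ggplot2::ggplot(series, ggplot2::aes(x = .data[[xvar]], y = .data[[yvar]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xvar, y = yvar)
}
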