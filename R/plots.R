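# ggplot2 views of the result types.

#' Map a per-pixel result column on the grid
#'
#' @param data Tibble with `row`, `col` (or `lon`, `lat`) and the mapped
#'   column.
#' @param fill Column to map, as a string.
#' @return A ggplot object.
#' @export
plot_pixel_map <- function(data, fill) {
  stopifnot(fill %in% names(data))
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$lon, y = .data$lat,
    fill = .data[[fill]]
  )) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}

#' Trend-class map
#'
#' @param trend A [trend_map()] result.
#' @param what `"class"`, `"slope"` or `"cv"`.
#' @return A ggplot object.
#' @export
plot_trend_map <- function(trend, what = c("class", "slope", "cv")) {
  what <- match.arg(what)
  p <- plot_pixel_map(trend, what)
  if (what == "slope") {
    p <- p + ggplot2::scale_fill_gradient2(low = "sienna", high = "darkgreen")
  }
  p + ggplot2::labs(fill = what)
}

#' @rdname hovmoller
#' @param object A `hovmoller` section.
#' @param ... Unused.
#' @export
autoplot.hovmoller <- function(object, ...) {
  axis_lab <- if (attr(object, "axis") == "latitude") {
    "Latitude"
  } else {
    "Longitude"
  }
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$year, y = .data$bin_mid,
    fill = .data$z
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(
      low = "sienna", mid = "white",
      high = "darkgreen"
    ) +
    ggplot2::labs(x = "Year", y = axis_lab, fill = "z-score") +
    ggplot2::theme_minimal()
}

#' @rdname eof_decompose
#' @param object An `eof` object.
#' @param mode Mode to display.
#' @export
autoplot.eof <- function(object, mode = 1, ...) {
  sp <- dplyr::filter(object$spatial, .data$mode == !!mode)
  plot_pixel_map(sp, "loading") +
    ggplot2::scale_fill_gradient2(low = "sienna", high = "darkgreen") +
    ggplot2::ggtitle(sprintf(
      "EOF mode %d (%.1f%% of variance)",
      mode, 100 * object$variance_fraction[mode]
    ))
}

#' Future-trend class map
#'
#' @param persistence A [persistence_map()] result.
#' @return A ggplot object.
#' @export
plot_future_trend <- function(persistence) {
  plot_pixel_map(persistence, "future_class") +
    ggplot2::labs(fill = "Future trend")
}
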