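#' Plot methods for result objects
#'
#' @param object The result object.
#' @param scale Plot the response on the logit or probability scale.
#' @param smoothed Plot the 30-year running mean instead of raw areas.
#' @param ... Unused.
#' @return A ggplot object.
#' @name eelgrass-autoplot
#' @method autoplot response_curve
#' @export
autoplot.response_curve <- function(object, scale = c("logit", "probability"),
                                    ...) {
  scale <- match.arg(scale)
  if (scale == "logit") {
    y <- "effect"
    lo <- "lower"
    hi <- "upper"
    ylab <- "partial effect (logit)"
  } else {
    y <- "probability"
    lo <- "probability_lower"
    hi <- "probability_upper"
    ylab <- "probability of occurrence"
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data[[lo]], ymax = .data[[hi]]),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[y]])) +
    ggplot2::labs(x = unique(object$predictor), y = ylab) +
    ggplot2::theme_minimal()
}

#' @rdname eelgrass-autoplot
#' @method autoplot area_series
#' @export
autoplot.area_series <- function(object, smoothed = TRUE, ...) {
  y <- if (smoothed) "area_smoothed" else "area_km2"
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$year, y = .data[[y]], colour = .data$wave,
                 linetype = .data$nutrient)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year", y = "eelgrass area (km²)",
                  colour = "wave realization", linetype = "nutrients") +
    ggplot2::theme_minimal()
}

#' @rdname eelgrass-autoplot
#' @method autoplot depth_profile
#' @export
autoplot.depth_profile <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = (.data$bin_lower + .data$bin_upper) / 2,
                 y = .data$percent_change)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "water depth (m)", y = "coverage change (%)") +
    ggplot2::theme_minimal()
}

#' Plot one occurrence probability map
#'
#' @param map A probability map (`row`, `col`, `probability`) or a
#'   difference map (`row`, `col`, `delta`).
#' @return A ggplot raster of the field (shoreline at the top).
#' @export
plot_probability_map <- function(map) {
  value <- if ("delta" %in% names(map)) "delta" else "probability"
  p <- ggplot2::ggplot(
    map,
    ggplot2::aes(x = .data$col, y = .data$row, fill = .data[[value]])
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = value) +
    ggplot2::theme_minimal()
  if (value == "delta") {
    p + ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                      high = "seagreen", midpoint = 0)
  } else {
    p + ggplot2::scale_fill_viridis_c(limits = c(0, 1))
  }
}
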