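# ggplot2 visualizations of fits and band reports.

# internal: sample points along a fitted ellipse/circle boundary
fit_boundary <- function(fit, n = 361L) {
  tt <- seq(0, 2 * pi, length.out = n)
  if (inherits(fit, "ellipse_fit")) {
    g <- fit$geom
    tibble(x = g$xc + g$m * cos(tt) * cos(g$theta) - g$n * sin(tt) * sin(g$theta),
           y = g$yc + g$m * cos(tt) * sin(g$theta) + g$n * sin(tt) * cos(g$theta))
  } else {
    g <- fit$geom
    tibble(x = g$xc + g$r * cos(tt), y = g$yc + g$r * sin(tt))
  }
}

#' @describeIn fit_plots Ellipse fit over its contour points.
#' @method autoplot ellipse_fit
#' @export
autoplot.ellipse_fit <- function(object, ...) {
  fit_plot_impl(object, "direct least-squares ellipse fit")
}

#' @describeIn fit_plots Circle fit over its contour points.
#' @method autoplot circle_fit
#' @export
autoplot.circle_fit <- function(object, ...) {
  fit_plot_impl(object, "least-squares circle fit")
}

#' Plot fitted eye and iris geometry
#'
#' `autoplot()` methods drawing the contour points and the fitted curve in
#' image coordinates (y axis reversed so the origin is top-left, as in the
#' rasters).
#'
#' @param object An `ellipse_fit` or `circle_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name fit_plots
NULL

fit_plot_impl <- function(fit, title) {
  ggplot2::ggplot(fit$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_path(data = fit_boundary(fit), color = "red") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Scatter plots of eye area against eyebrow curvature per band
#'
#' @param object A [curvature_eye_trend()] result.
#' @param ... Unused.
#' @return A ggplot object, faceted by score band, with the OLS trend line.
#' @method autoplot curvature_trend
#' @export
autoplot.curvature_trend <- function(object, ...) {
  scatter <- attr(object, "scatter")
  ggplot2::ggplot(scatter, ggplot2::aes(x = .data$curvature, y = .data$eye_area)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "red", linewidth = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$band)) +
    ggplot2::labs(x = "eyebrow curvature (px)", y = expression("eye area" ~ (px^2))) +
    ggplot2::theme_minimal()
}

#' Bar charts of per-band feature histograms
#'
#' @param histograms A [feature_histograms()] table.
#' @param feature Feature column to plot.
#' @return A ggplot object, one bar per interval, faceted by band.
#' @export
plot_feature_histogram <- function(histograms, feature) {
  dat <- dplyr::filter(histograms, .data$feature == !!feature)
  if (nrow(dat) == 0L) abort(paste0("no histogram rows for feature ", feature))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$band)) +
    ggplot2::labs(x = feature, y = "number of images") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Mean face ratio against curvature interval per band
#'
#' @param ratio_bins A [ratio_by_curvature_bins()] table.
#' @return A ggplot object: one line per band over the interval midpoints.
#' @export
plot_ratio_by_curvature <- function(ratio_bins) {
  ggplot2::ggplot(ratio_bins,
                  ggplot2::aes(x = .data$bin_mid, y = .data$mean_ratio,
                               color = .data$band, group = .data$band)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "eyebrow curvature interval midpoint (px)",
                  y = "mean D1/D2") +
    ggplot2::theme_minimal()
}
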