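# broom-style tidiers for the fitted geometry objects.

#' Tidy an ellipse fit
#'
#' @param x An `ellipse_fit`.
#' @param ... Unused.
#' @return A tibble with one row per quantity: the six conic coefficients
#'   (normalized so `4ac - b^2 = 1`) and the derived geometry.
#' @method tidy ellipse_fit
#' @export
tidy.ellipse_fit <- function(x, ...) {
  tibble(term = c(names(x$coeffs), "xc", "yc", "m", "n", "theta", "area"),
         estimate = c(unname(x$coeffs), x$geom$xc, x$geom$yc, x$geom$m,
                      x$geom$n, x$geom$theta, x$geom$area))
}

#' Glance at an ellipse fit
#'
#' @param x An `ellipse_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n` points, `rss` (summed squared algebraic
#'   distances), `constraint` (the value of `4ac - b^2`, 1 by
#'   construction), `lambda` (the positive generalized eigenvalue).
#' @method glance ellipse_fit
#' @export
glance.ellipse_fit <- function(x, ...) {
  A <- x$coeffs
  tibble(n = x$n, rss = x$rss,
         constraint = 4 * A[["a"]] * A[["c"]] - A[["b"]]^2,
         lambda = x$lambda)
}

#' Tidy a circle fit
#'
#' @param x A `circle_fit`.
#' @param ... Unused.
#' @return A tibble of the algebraic coefficients and derived geometry.
#' @method tidy circle_fit
#' @export
tidy.circle_fit <- function(x, ...) {
  tibble(term = c(names(x$coeffs), "xc", "yc", "r", "area"),
         estimate = c(unname(x$coeffs), x$geom$xc, x$geom$yc, x$geom$r,
                      x$geom$area))
}

#' Glance at a circle fit
#'
#' @param x A `circle_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `rss` (the minimized objective value).
#' @method glance circle_fit
#' @export
glance.circle_fit <- function(x, ...) {
  tibble(n = x$n, rss = x$rss)
}
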