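# Eye model: Sobel edge extraction on the normalized patch, contour
# selection, direct least-squares ellipse fitting of the eye contour under
# the constraint 4ac - b^2 = 1, and algebraic least-squares circle fitting
# of the iris contour.

#' Sobel edge mask of a patch
#'
#' Gradient magnitude from the 3x3 Sobel kernels (replicate padding),
#' binarized at a fraction of the maximum magnitude.
#'
#' @param patch Grayscale matrix.
#' @param magnitude_threshold Fraction of the maximum gradient magnitude at
#'   which a pixel becomes edge foreground. Default 0.25.
#' @return Binary mask (`{0, 255}`); a constant image gives an empty mask.
#' @export
sobel_edges <- function(patch, magnitude_threshold = 0.25) {
  check_gray(patch)
  sh <- function(dr, dc) {
    ri <- pmin(pmax(seq_len(nrow(patch)) + dr, 1L), nrow(patch))
    ci <- pmin(pmax(seq_len(ncol(patch)) + dc, 1L), ncol(patch))
    patch[ri, ci, drop = FALSE]
  }
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  mag <- sqrt(gx^2 + gy^2)
  out <- matrix(0, nrow(patch), ncol(patch))
  mx <- max(mag)
  if (mx > 0) out[mag >= magnitude_threshold * mx] <- 255
  out
}

#' Extract the eye contour from an edge mask
#'
#' Interference correction and contour selection: the edge mask is
#' morphologically closed (3x3 box) and the largest 8-connected component
#' is selected. A provisional ellipse is fitted to the component's outer
#' envelope (per-column and per-row extremal pixels) — the envelope anchors
#' the provisional fit on the eye outline even when the iris edge band
#' touches it and is absorbed into the same component. Component points are
#' then trimmed iteratively: each round keeps the points whose signed
#' radial distance from the current fitted ellipse lies within `band_px`
#' of the median distance, and refits. The band halfwidth matches the edge
#' band a thresholded 3x3 Sobel operator paints around a contour (about
#' two pixels), so starting from the envelope the trimming converges onto
#' the full (two-sided) edge band of the eye outline — the final fit is
#' not biased outward — while iris points and stragglers fall away.
#'
#' @param edges Binary edge mask.
#' @param close Apply the 3x3 morphological closing first? Default `TRUE`.
#' @param envelope Seed the provisional fit with the outer envelope?
#'   Default `TRUE`.
#' @param band_px Trim-band halfwidth in pixels. Default 2.
#' @param iters Trim-refit rounds. Default 3.
#' @return A tibble of 0-based `x`, `y` contour points (`>= 5` rows).
#' @export
extract_eye_contour <- function(edges, close = TRUE, envelope = TRUE,
                                band_px = 2, iters = 3) {
  check_mask(edges)
  if (!any(edges > 0)) abort("contour too small: empty edge mask")
  work <- edges
  if (close) {
    closed <- EBImage::closing(work > 0, EBImage::makeBrush(3, shape = "box"))
    work <- matrix(0, nrow(edges), ncol(edges))
    work[EBImage::imageData(closed) > 0] <- 255
  }
  lab <- label_components(work, 8)
  sizes <- tabulate(lab[lab > 0L], nbins = max(1L, max(lab)))
  big <- which.max(sizes)
  idx <- which(lab == big, arr.ind = TRUE)
  pts <- tibble(x = as.numeric(idx[, 2L] - 1L), y = as.numeric(idx[, 1L] - 1L))
  seed_pts <- if (envelope) outer_envelope(pts) else pts
  if (nrow(seed_pts) < 5L) abort("contour too small: largest component has < 5 points")
  fit <- tryCatch(fit_ellipse_direct(seed_pts), error = function(e) NULL)
  for (it in seq_len(iters)) {
    if (is.null(fit)) break
    d <- ellipse_radial_distance(pts, fit$geom)
    keep <- abs(d - median(d)) <= band_px
    if (sum(keep) < 5L || all(keep)) break
    pts <- pts[keep, ]
    fit <- tryCatch(fit_ellipse_direct(pts), error = function(e) fit)
  }
  if (nrow(pts) < 5L) abort("contour too small: largest component has < 5 points")
  pts
}

# internal: per-column and per-row extremal pixels of a point set
outer_envelope <- function(pts) {
  by_col <- dplyr::group_by(pts, .data$x)
  col_ext <- dplyr::summarise(by_col, ymin = min(.data$y), ymax = max(.data$y),
                              .groups = "drop")
  by_row <- dplyr::group_by(pts, .data$y)
  row_ext <- dplyr::summarise(by_row, xmin = min(.data$x), xmax = max(.data$x),
                              .groups = "drop")
  env <- dplyr::bind_rows(
    tibble(x = col_ext$x, y = col_ext$ymin),
    tibble(x = col_ext$x, y = col_ext$ymax),
    tibble(x = row_ext$xmin, y = row_ext$y),
    tibble(x = row_ext$xmax, y = row_ext$y))
  dplyr::distinct(env)
}

#' Extract the iris contour from an edge mask
#'
#' Edge points strictly interior to the fitted eye ellipse shrunk by an
#' interiority factor, separating iris edges from the eye outline. A
#' provisional circle fit then trims points whose radial distance from the
#' current circle deviates from the median by more than `band_px` pixels
#' (leftover inner-edge pixels of the eye outline that slip past the
#' interiority cut), refitting between rounds.
#'
#' @param edges Binary edge mask.
#' @param eye An `ellipse_fit` (or its `geom` row) for the eye contour.
#' @param factor Interiority factor in `(0, 1]`: points must lie inside the
#'   ellipse with both semi-axes scaled by this factor. Default 0.9.
#' @param band_px Trim-band halfwidth in pixels. Default 2.
#' @param iters Trim-refit rounds. Default 2.
#' @return A tibble of 0-based `x`, `y` candidate iris points (`>= 3` rows).
#' @export
extract_iris_contour <- function(edges, eye, factor = 0.9, band_px = 2,
                                 iters = 2) {
  check_mask(edges)
  geom <- if (inherits(eye, "ellipse_fit")) eye$geom else eye
  idx <- which(edges > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("iris not found: empty edge mask")
  x <- idx[, 2L] - 1; y <- idx[, 1L] - 1
  ct <- cos(geom$theta); st <- sin(geom$theta)
  xp <- ct * (x - geom$xc) + st * (y - geom$yc)
  yp <- -st * (x - geom$xc) + ct * (y - geom$yc)
  inside <- (xp / (factor * geom$m))^2 + (yp / (factor * geom$n))^2 < 1
  if (sum(inside) < 3L) abort("iris not found: fewer than 3 interior edge points")
  pts <- tibble(x = x[inside], y = y[inside])
  fit <- tryCatch(fit_circle_lsq(pts), error = function(e) NULL)
  for (it in seq_len(iters)) {
    if (is.null(fit)) break
    d <- sqrt((pts$x - fit$geom$xc)^2 + (pts$y - fit$geom$yc)^2) - fit$geom$r
    keep <- abs(d - median(d)) <= band_px
    if (sum(keep) < 3L || all(keep)) break
    pts <- pts[keep, ]
    fit <- tryCatch(fit_circle_lsq(pts), error = function(e) fit)
  }
  pts
}

#' Constraint matrix of the direct ellipse fit
#'
#' The 6x6 matrix `C` expressing the ellipse constraint as the quadratic
#' form `A^T C A = 4ac - b^2` on conic coefficients `A = (a,b,c,d,e,f)`.
#' Its eigenvalues are `{-2, -1, 2, 0, 0, 0}`.
#'
#' @return A 6x6 numeric matrix.
#' @export
constraint_matrix <- function() {
  C <- matrix(0, 6, 6)
  C[1, 3] <- 2; C[3, 1] <- 2; C[2, 2] <- -1
  C
}

#' Direct least-squares ellipse fit
#'
#' Fits the conic `a x^2 + b x y + c y^2 + d x + e y + f = 0` to scattered
#' points by minimizing the summed squared algebraic distances subject to
#' `4ac - b^2 = 1`. The constrained problem reduces to the generalized
#' eigenproblem `S A = lambda C A` (scatter matrix `S = D^T D`, constraint
#' matrix `C`), whose unique positive generalized eigenvalue carries the
#' ellipse solution; it is solved by the numerically stable block
#' partitioning of the design matrix, and the eigenvector is scaled by
#' `mu = 1 / sqrt(u^T C u)` so that the constraint holds exactly. Input
#' coordinates are centered and isotropically scaled internally for
#' conditioning; coefficients are mapped back and renormalized.
#'
#' @param points A data frame (or matrix) of at least 5 `x`, `y` points.
#' @return An object of class `ellipse_fit`: list with `coeffs` (named
#'   vector `a..f` satisfying `4ac - b^2 = 1`), `geom` (one-row tibble
#'   `xc`, `yc`, `m`, `n`, `theta`, `area` with `m >= n` and
#'   `area = pi * m * n`), `points`, `n`, and `rss` (summed squared
#'   algebraic distances of the normalized coefficients).
#' @export
fit_ellipse_direct <- function(points) {
  pts <- as_points(points, min_n = 5L, what = "ellipse fit")
  x <- pts$x; y <- pts$y
  mx <- mean(x); my <- mean(y)
  s <- sqrt(mean((x - mx)^2 + (y - my)^2) / 2)
  if (!is.finite(s) || s < 1e-12) abort("ellipse fit failed: degenerate points")
  u <- (x - mx) / s; v <- (y - my) / s

  D1 <- cbind(u^2, u * v, v^2)
  D2 <- cbind(u, v, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    abort("ellipse fit failed: collinear or degenerate points"))
  M <- S1 + S2 %*% Tm
  Cinv <- matrix(c(0, 0, 0.5, 0, -1, 0, 0.5, 0, 0), 3, 3)
  eg <- eigen(Cinv %*% M)
  ok <- abs(Im(eg$values)) < 1e-8
  a1 <- NULL; lambda <- NA_real_
  for (k in which(ok)) {
    vec <- Re(eg$vectors[, k])
    if (4 * vec[1] * vec[3] - vec[2]^2 > 0) { a1 <- vec; lambda <- Re(eg$values[k]); break }
  }
  if (is.null(a1)) abort("ellipse fit failed: no positive generalized eigenvalue")
  A0 <- c(a1, as.numeric(Tm %*% a1))

  # map coefficients back to the original frame
  a <- A0[1] / s^2; b <- A0[2] / s^2; c_ <- A0[3] / s^2
  d <- A0[4] / s - (2 * A0[1] * mx + A0[2] * my) / s^2
  e <- A0[5] / s - (A0[2] * mx + 2 * A0[3] * my) / s^2
  f <- A0[6] + (A0[1] * mx^2 + A0[2] * mx * my + A0[3] * my^2) / s^2 -
    (A0[4] * mx + A0[5] * my) / s
  A <- c(a, b, c_, d, e, f)
  disc <- 4 * A[1] * A[3] - A[2]^2
  if (!is.finite(disc) || disc <= 0) abort("ellipse fit failed: not an ellipse")
  A <- A / sqrt(disc)                 # mu-normalization: A^T C A = 1
  if (A[1] + A[3] < 0) A <- -A        # sign convention so semi-axes are real
  names(A) <- c("a", "b", "c", "d", "e", "f")

  geom <- conic_geometry(A)
  structure(list(coeffs = A, geom = geom, points = pts, n = nrow(pts),
                 lambda = lambda,
                 rss = sum(conic_eval(A, x, y)^2)),
            class = "ellipse_fit")
}

#' Algebraic least-squares circle fit
#'
#' Fits `x^2 + y^2 + a x + b y + c = 0` by linear least squares (the 3x3
#' normal equations in `a`, `b`, `c`, solved by QR), then converts to
#' center `(-a/2, -b/2)` and radius `sqrt(a^2 + b^2 - 4c) / 2`.
#'
#' @param points A data frame (or matrix) of at least 3 non-collinear
#'   `x`, `y` points.
#' @return An object of class `circle_fit`: list with `coeffs` (named
#'   `a`, `b`, `c`), `geom` (one-row tibble `xc`, `yc`, `r`, `area` with
#'   `area = pi r^2`), `points`, `n`, and `rss` (the minimized objective).
#' @export
fit_circle_lsq <- function(points) {
  pts <- as_points(points, min_n = 3L, what = "circle fit")
  x <- pts$x; y <- pts$y
  X <- cbind(x, y, 1)
  rhs <- -(x^2 + y^2)
  qrX <- qr(X)
  if (qrX$rank < 3L) abort("circle fit failed: collinear points")
  abc <- unname(qr.coef(qrX, rhs))
  r2 <- (abc[1]^2 + abc[2]^2 - 4 * abc[3])
  if (!is.finite(r2) || r2 <= 0) abort("circle fit failed: nonpositive radius")
  r <- 0.5 * sqrt(r2)
  res <- x^2 + y^2 + abc[1] * x + abc[2] * y + abc[3]
  structure(list(coeffs = setNames(as.numeric(abc), c("a", "b", "c")),
                 geom = tibble(xc = -0.5 * abc[[1]], yc = -0.5 * abc[[2]],
                               r = r, area = pi * r^2),
                 points = pts, n = nrow(pts), rss = sum(res^2)),
            class = "circle_fit")
}

#' Eye and iris features of a normalized eye patch
#'
#' Full pipeline: Sobel edges, eye-contour extraction, direct ellipse fit,
#' iris-contour extraction inside the fitted ellipse, circle fit, and the
#' iris-to-eye area ratio.
#'
#' @param patch Normalized grayscale eye patch (typically 100 x 50).
#' @param magnitude_threshold Sobel binarization fraction. Default 0.25.
#' @param iris_factor Interiority factor for iris-point selection.
#'   Default 0.9.
#' @param details Also return the fit objects? Default `FALSE`.
#' @return A one-row tibble `eye_area`, `iris_area`, `iris_ratio`,
#'   `fit_flags` (`"ok"`, or `"iris_ratio>1"` when the fitted iris exceeds
#'   the fitted eye). With `details = TRUE`, a list with `features`,
#'   `eye_fit`, `iris_fit`, `edges`.
#' @export
eye_features <- function(patch, magnitude_threshold = 0.25, iris_factor = 0.9,
                         details = FALSE) {
  stage <- function(lab, expr) {
    tryCatch(expr, error = function(e)
      abort(paste0(lab, ": ", conditionMessage(e))))
  }
  edges <- stage("edge-detection", sobel_edges(patch, magnitude_threshold))
  eye_pts <- stage("eye-contour", extract_eye_contour(edges))
  eye_fit <- stage("eye-fit", fit_ellipse_direct(eye_pts))
  iris_pts <- stage("iris-contour", extract_iris_contour(edges, eye_fit, iris_factor))
  iris_fit <- stage("iris-fit", fit_circle_lsq(iris_pts))
  ratio <- iris_fit$geom$area / eye_fit$geom$area
  flags <- if (ratio > 1) "iris_ratio>1" else "ok"
  if (ratio > 1) warn("fitted iris area exceeds fitted eye area")
  feats <- tibble(eye_area = eye_fit$geom$area, iris_area = iris_fit$geom$area,
                  iris_ratio = ratio, fit_flags = flags)
  if (details) list(features = feats, eye_fit = eye_fit, iris_fit = iris_fit,
                    edges = edges)
  else feats
}

# internal helpers ----------------------------------------------------------

# elliptical radius fraction of points (1 = on the ellipse, < 1 inside)
ellipse_radius_fraction <- function(pts, geom) {
  ct <- cos(geom$theta); st <- sin(geom$theta)
  xp <- ct * (pts$x - geom$xc) + st * (pts$y - geom$yc)
  yp <- -st * (pts$x - geom$xc) + ct * (pts$y - geom$yc)
  sqrt((xp / geom$m)^2 + (yp / geom$n)^2)
}

# approximate signed radial distance (px) to the ellipse along the center
# ray: negative inside, zero on the boundary
ellipse_radial_distance <- function(pts, geom) {
  q <- ellipse_radius_fraction(pts, geom)
  r <- sqrt((pts$x - geom$xc)^2 + (pts$y - geom$yc)^2)
  r * (q - 1) / pmax(q, 1e-9)
}

as_points <- function(points, min_n, what) {
  if (is.matrix(points)) points <- as.data.frame(points)
  if (!all(c("x", "y") %in% names(points))) {
    names(points)[1:2] <- c("x", "y")
  }
  pts <- tibble(x = as.numeric(points$x), y = as.numeric(points$y))
  if (nrow(pts) < min_n || anyNA(pts)) {
    abort(paste0(what, " failed: needs at least ", min_n, " finite points"))
  }
  pts
}

conic_eval <- function(A, x, y) {
  A[1] * x^2 + A[2] * x * y + A[3] * y^2 + A[4] * x + A[5] * y + A[6]
}

# center, semi-axes (m >= n), orientation and area from conic coefficients
conic_geometry <- function(A) {
  a <- A[[1]]; b <- A[[2]]; c_ <- A[[3]]; d <- A[[4]]; e <- A[[5]]; f <- A[[6]]
  disc <- 4 * a * c_ - b^2
  xc <- (b * e - 2 * c_ * d) / disc
  yc <- (b * d - 2 * a * e) / disc
  g <- a * xc^2 + c_ * yc^2 + b * xc * yc - f
  root <- sqrt((a - c_)^2 + b^2)
  m2 <- 2 * g / (a + c_ - root)
  n2 <- 2 * g / (a + c_ + root)
  if (!is.finite(m2) || !is.finite(n2) || m2 <= 0 || n2 <= 0) {
    abort("ellipse fit failed: degenerate conic geometry")
  }
  # orientation of the major axis: eigenvector of the smaller eigenvalue of
  # [[a, b/2], [b/2, c]]
  theta <- 0.5 * atan2(-b, c_ - a)
  tibble(xc = xc, yc = yc, m = sqrt(m2), n = sqrt(n2), theta = theta,
         area = pi * sqrt(m2) * sqrt(n2))
}

#' @export
print.ellipse_fit <- function(x, ...) {
  g <- x$geom
  cat(sprintf("<ellipse_fit> n = %d | center (%.3f, %.3f) | semi-axes %.3f / %.3f | area %.2f\n",
              x$n, g$xc, g$yc, g$m, g$n, g$area))
  invisible(x)
}

#' @export
print.circle_fit <- function(x, ...) {
  g <- x$geom
  cat(sprintf("<circle_fit> n = %d | center (%.3f, %.3f) | radius %.3f | area %.2f\n",
              x$n, g$xc, g$yc, g$r, g$area))
  invisible(x)
}
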