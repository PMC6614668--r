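# Independent oracles and small fixture builders used across the suite.

# brute-force maximum chord-to-point distance: vector cross-product form,
# independent of the line-coefficient route used by the package
brute_curvature <- function(pts) {
  p1 <- c(pts$x[1], pts$y[1])
  p2 <- c(pts$x[nrow(pts)], pts$y[nrow(pts)])
  v <- p2 - p1
  interior <- pts[-c(1, nrow(pts)), ]
  max(abs(v[1] * (interior$y - p1[2]) - v[2] * (interior$x - p1[1])) /
        sqrt(sum(v^2)))
}

# brute-force minimizer of the algebraic circle objective
# F(a,b,c) = sum (x^2 + y^2 + a x + b y + c)^2
brute_circle <- function(x, y) {
  obj <- function(p) sum((x^2 + y^2 + p[1] * x + p[2] * y + p[3])^2)
  start <- c(-2 * mean(x), -2 * mean(y),
             mean(x)^2 + mean(y)^2 - mean((x - mean(x))^2 + (y - mean(y))^2))
  fit <- optim(start, obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  a <- fit$par[1]; b <- fit$par[2]; c_ <- fit$par[3]
  c(xc = -a / 2, yc = -b / 2, r = 0.5 * sqrt(a^2 + b^2 - 4 * c_))
}

# points sampled on an ellipse (uniform parameter angle)
ellipse_points <- function(n, xc, yc, m, semi_n, theta = 0, noise_sd = 0) {
  tt <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- xc + m * cos(tt) * cos(theta) - semi_n * sin(tt) * sin(theta)
  y <- yc + m * cos(tt) * sin(theta) + semi_n * sin(tt) * cos(theta)
  if (noise_sd > 0) {
    x <- x + rnorm(n, 0, noise_sd)
    y <- y + rnorm(n, 0, noise_sd)
  }
  data.frame(x = x, y = y)
}

# mask with value 255 at the given 0-based (x, y) pixels
mask_from_pixels <- function(width, height, xy) {
  m <- matrix(0, height, width)
  m[cbind(xy[, 2] + 1, xy[, 1] + 1)] <- 255
  m
}

# a curve object from bare points (curvature only looks at $points)
curve_from_points <- function(x, y) {
  structure(list(points = tibble::tibble(x = x, y = y),
                 raster = matrix(0, 1, 1)),
            class = "eyebrow_curve")
}

# number of generalized eigenvalues of S A = lambda C A with lambda > 0,
# via the eigenvalues of S^-1 C (lambda = 1 / mu for nonzero mu)
count_positive_gen_eigenvalues <- function(S, C) {
  mu <- eigen(solve(S) %*% C, only.values = TRUE)$values
  mu <- Re(mu[abs(Im(mu)) < 1e-8])
  mu <- mu[abs(mu) > 1e-10 * max(abs(mu))]
  sum(1 / mu > 0)
}
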