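test_that("sobel edges localize a step and vanish on constant images", {
  step <- matrix(80, 50, 100); step[, 51:100] <- 220
  edges <- sobel_edges(step)
  cols <- which(apply(edges > 0, 2, any)) - 1
  expect_true(all(abs(cols - 49.5) <= 2))

  expect_true(all(sobel_edges(matrix(42, 30, 30)) == 0))

  ey <- gen_eye(semi_axes = c(30, 15), iris_radius = 10, noise_sd = 0, seed = 1)
  edges2 <- sobel_edges(ey$image)
  tt <- seq(0, 2 * pi, length.out = 361)[-361]
  ex <- 50 + 30 * cos(tt); eyy <- 25 + 15 * sin(tt)
  idx <- which(edges2 > 0, arr.ind = TRUE)
  px <- idx[, 2] - 1; py <- idx[, 1] - 1
  covered <- vapply(seq_along(tt), function(k) {
    min((px - ex[k])^2 + (py - eyy[k])^2) <= 1
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("eye contour extraction keeps the dominant ring and drops interference", {
  tt <- seq(0, 2 * pi, length.out = 400)[-400]
  ring <- unique(round(cbind(50 + 25 * cos(tt), 25 + 12 * sin(tt))))
  strays <- rbind(c(2, 2), c(95, 3), c(3, 46))
  edges <- mask_from_pixels(100, 50, rbind(ring, strays))
  pts <- extract_eye_contour(edges, close = FALSE)
  q <- sqrt(((pts$x - 50) / 25)^2 + ((pts$y - 25) / 12)^2)
  expect_true(all(abs(q - 1) < 0.25))       # on the ring, never at the strays
  expect_false(any(pts$x < 10 & pts$y < 10))

  inner <- unique(round(cbind(50 + 10 * cos(tt), 25 + 6 * sin(tt))))
  both <- mask_from_pixels(100, 50, rbind(ring, inner))
  pts2 <- extract_eye_contour(both, close = FALSE)
  q2 <- sqrt(((pts2$x - 50) / 25)^2 + ((pts2$y - 25) / 12)^2)
  expect_true(all(q2 > 0.8))                # outer ring selected

  expect_error(extract_eye_contour(matrix(0, 50, 100)), "contour too small")
  expect_error(extract_eye_contour(mask_from_pixels(100, 50, cbind(5, 5))),
               "contour too small")
})

test_that("generator eye contours land within 1.5 px of the true ellipse", {
  ey <- gen_eye(semi_axes = c(30, 15), iris_radius = 10, seed = 2)
  pts <- extract_eye_contour(sobel_edges(ey$image))
  tt <- seq(0, 2 * pi, length.out = 721)[-721]
  ex <- 50 + 30 * cos(tt); eyy <- 25 + 15 * sin(tt)
  d <- vapply(seq_len(nrow(pts)), function(i) {
    sqrt(min((pts$x[i] - ex)^2 + (pts$y[i] - eyy)^2))
  }, numeric(1))
  expect_gte(mean(d <= 1.5), 0.8)
})

test_that("iris contour selection is strictly interior and tangent arcs are excluded", {
  ey <- gen_eye(semi_axes = c(30, 15), iris_radius = 12, seed = 3)
  det <- eye_features(ey$image, details = TRUE)
  iris_pts <- extract_iris_contour(det$edges, det$eye_fit)
  d <- abs(sqrt((iris_pts$x - 50)^2 + (iris_pts$y - 25)^2) - 12)
  expect_gte(mean(d <= 1.5), 0.8)

  tt <- seq(0, 2 * pi, length.out = 500)[-500]
  ring <- unique(round(cbind(50 + 30 * cos(tt), 25 + 15 * sin(tt))))
  edges <- mask_from_pixels(100, 50, ring)
  eye_fit <- fit_ellipse_direct(extract_eye_contour(edges, close = FALSE))
  expect_error(extract_iris_contour(edges, eye_fit), "iris not found")

  # circle internally tangent at the ellipse bottom: shared-arc pixels are
  # excluded by the interiority factor
  circ <- unique(round(cbind(50 + 10 * cos(tt), 30 + 10 * sin(tt))))
  both <- mask_from_pixels(100, 50, rbind(ring, circ))
  ipts <- extract_iris_contour(both, eye_fit)
  expect_true(all(ipts$y < 39))
})

test_that("the constraint matrix has the printed spectrum and quadratic form", {
  C <- constraint_matrix()
  expect_equal(C, t(C))
  expect_equal(sort(eigen(C)$values), c(-2, -1, 0, 0, 0, 2))
  set.seed(8)
  for (i in 1:20) {
    A <- runif(6, -3, 3)
    expect_equal(drop(t(A) %*% C %*% A), 4 * A[1] * A[3] - A[2]^2,
                 tolerance = 1e-12)
  }
})

test_that("the direct ellipse fit is exact on noiseless conics", {
  f <- fit_ellipse_direct(ellipse_points(100, 50, 25, 30, 15))
  expect_equal(f$geom$xc, 50, tolerance = 1e-6)
  expect_equal(f$geom$yc, 25, tolerance = 1e-6)
  expect_equal(f$geom$m, 30, tolerance = 1e-6)
  expect_equal(f$geom$n, 15, tolerance = 1e-6)
  expect_equal(f$geom$area, pi * 450, tolerance = 1e-6)

  fc <- fit_ellipse_direct(ellipse_points(50, 0, 0, 10, 10))
  expect_equal(fc$geom$m, 10, tolerance = 1e-6)
  expect_equal(fc$geom$n, 10, tolerance = 1e-6)

  A <- f$coeffs
  expect_equal(drop(t(A) %*% constraint_matrix() %*% A), 1, tolerance = 1e-9)
  expect_equal(4 * A[["a"]] * A[["c"]] - A[["b"]]^2, 1, tolerance = 1e-9)

  expect_error(fit_ellipse_direct(data.frame(x = 1:10, y = 2 * (1:10) + 3)),
               "ellipse fit failed")
})

test_that("the ellipse fit is equivariant under translation and uniform scaling", {
  set.seed(31)
  pts <- ellipse_points(60, 20, 30, 18, 9, theta = 0.4, noise_sd = 0.3)
  f0 <- fit_ellipse_direct(pts)
  f1 <- fit_ellipse_direct(data.frame(x = pts$x + 13.5, y = pts$y - 7.25))
  expect_equal(f1$geom$xc, f0$geom$xc + 13.5, tolerance = 1e-6)
  expect_equal(f1$geom$yc, f0$geom$yc - 7.25, tolerance = 1e-6)
  expect_equal(f1$geom$m, f0$geom$m, tolerance = 1e-6)
  expect_equal(f1$geom$n, f0$geom$n, tolerance = 1e-6)

  s <- 2.5
  f2 <- fit_ellipse_direct(data.frame(x = s * pts$x, y = s * pts$y))
  expect_equal(f2$geom$m, s * f0$geom$m, tolerance = 1e-6)
  expect_equal(f2$geom$n, s * f0$geom$n, tolerance = 1e-6)
  expect_equal(f2$geom$area, s^2 * f0$geom$area, tolerance = 1e-4)
})

test_that("the generalized eigenproblem has a unique positive eigenvalue", {
  set.seed(77)
  C <- constraint_matrix()
  for (i in 1:200) {
    pts <- ellipse_points(sample(20:60, 1),
                          runif(1, 20, 80), runif(1, 10, 40),
                          runif(1, 8, 30), runif(1, 4, 15),
                          theta = runif(1, 0, pi), noise_sd = 0.2)
    D <- with(pts, cbind(x^2, x * y, y^2, x, y, 1))
    S <- crossprod(D)
    expect_equal(count_positive_gen_eigenvalues(S, C), 1)
    f <- fit_ellipse_direct(pts)
    expect_gt(f$lambda, 0)
  }
})

test_that("the circle fit solves the normal equations exactly and under noise", {
  cf <- fit_circle_lsq(data.frame(x = c(0, 2, 0), y = c(0, 0, 2)))
  expect_equal(cf$geom$xc, 1)
  expect_equal(cf$geom$yc, 1)
  expect_equal(cf$geom$r, sqrt(2))
  expect_equal(cf$coeffs, c(a = -2, b = -2, c = 0))

  tt <- seq(0, 2 * pi, length.out = 51)[-51]
  cf2 <- fit_circle_lsq(data.frame(x = cos(tt), y = sin(tt)))
  expect_equal(cf2$geom$xc, 0, tolerance = 1e-9)
  expect_equal(cf2$geom$yc, 0, tolerance = 1e-9)
  expect_equal(cf2$geom$r, 1, tolerance = 1e-9)

  set.seed(12)
  noisy <- data.frame(x = cos(tt) + rnorm(50, 0, 0.05),
                      y = sin(tt) + rnorm(50, 0, 0.05))
  cf3 <- fit_circle_lsq(noisy)
  expect_lt(abs(cf3$geom$r - 1), 0.02)
  oracle <- brute_circle(noisy$x, noisy$y)
  expect_equal(unname(c(cf3$geom$xc, cf3$geom$yc, cf3$geom$r)), unname(oracle),
               tolerance = 1e-4)

  expect_error(fit_circle_lsq(data.frame(x = 1:5, y = 2 * (1:5))), "collinear")
})

test_that("the eye pipeline recovers planted areas and ratios", {
  ey <- gen_eye(semi_axes = c(30, 15), iris_radius = 12, seed = 1)
  f <- eye_features(ey$image)
  expect_lt(abs(f$eye_area - pi * 450) / (pi * 450), 0.10)
  expect_lt(abs(f$iris_ratio - 0.32) / 0.32, 0.15)
  expect_identical(f$fit_flags, "ok")

  # planted iris ratio 0.55 on a feasible (rounder) eye
  mn <- 22 * 16
  ey2 <- gen_eye(semi_axes = c(22, 16), iris_radius = sqrt(0.55 * mn), seed = 5)
  f2 <- eye_features(ey2$image)
  expect_gt(f2$iris_ratio, 0.45)
  expect_lt(f2$iris_ratio, 0.65)

  expect_error(eye_features(matrix(150, 50, 100)), "contour too small")
})

test_that("tidiers expose coefficients and constraint diagnostics", {
  f <- fit_ellipse_direct(ellipse_points(80, 40, 20, 25, 12, theta = 0.3))
  td <- tidy(f)
  expect_setequal(td$term[1:6], c("a", "b", "c", "d", "e", "f"))
  expect_equal(glance(f)$constraint, 1, tolerance = 1e-9)
  cf <- fit_circle_lsq(data.frame(x = c(0, 2, 0, 2), y = c(0, 0, 2, 2)))
  expect_equal(tidy(cf)$estimate[tidy(cf)$term == "r"], sqrt(2), tolerance = 1e-9)
  expect_equal(glance(cf)$n, 4)
})
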