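test_that("adaptive threshold resolves uniform images by polarity", {
  flat <- matrix(100, 30, 40)
  bright <- adaptive_threshold(flat, window = 15, offset = 5, "bright-foreground")
  expect_true(all(bright == 255))            # T = 95 everywhere, 100 >= 95
  dark <- adaptive_threshold(flat, window = 15, offset = 5, "dark-foreground")
  expect_true(all(dark == 0))
  expect_error(adaptive_threshold(flat, window = 14), "odd")
  expect_error(adaptive_threshold(flat, window = 1), "odd")
})

test_that("adaptive threshold segments a dark band against a light background", {
  img <- matrix(200, 50, 100)
  img[21:32, 11:90] <- 40                    # rows 20..31, cols 10..89 (0-based)
  mask <- adaptive_threshold(img, window = 15, offset = 2, "dark-foreground")
  margin <- 15
  band_interior <- mask[23:30, (11 + margin):(90 - margin)]
  expect_true(all(band_interior == 255))
  bg_interior <- mask[c(1:5, 45:50), (1 + margin):(100 - margin)]
  expect_true(all(bg_interior == 0))
})

test_that("eyebrow segmentation recovers a clean band and rejects pure noise", {
  eb <- gen_eyebrow(length = 95, width = 10, apex_height = 6, noise_blobs = 0,
                    noise_sd = 0, seed = 1)
  mask <- segment_eyebrow(eb$image)
  cc <- connected_components(mask)
  expect_equal(nrow(cc), 1)
  expect_lt(abs(sum(mask == 255) - 950) / 950, 0.05)

  salt <- matrix(200, 50, 100)
  set.seed(9)
  salt[cbind(sample(45, 25, TRUE) + 2, sample(95, 25, TRUE) + 2)] <- 30
  expect_error(segment_eyebrow(salt, patch_id = "noisy"), "no eyebrow found")

  stray <- gen_eyebrow(length = 85, width = 12, apex_height = 9,
                       noise_blobs = 3, noise_sd = 0, seed = 4)
  mask2 <- segment_eyebrow(stray$image)
  expect_equal(nrow(connected_components(mask2)), 1)
})

test_that("eyebrow area counts white pixels exactly", {
  expect_equal(eyebrow_area(matrix(255, 10, 10)), 100)
  expect_equal(eyebrow_area(matrix(0, 10, 10)), 0)
  rect <- matrix(0, 50, 100); rect[11:20, 21:50] <- 255
  expect_equal(eyebrow_area(rect), 300)
})

test_that("the midline curve takes per-column midpoints and rasterizes 8-connected", {
  m <- matrix(0, 50, 100)
  m[11:21, 6] <- 255                        # column x=5, rows 10..20
  m[13:15, 7] <- 255
  cv <- extract_curve(m)
  expect_equal(cv$points$y[cv$points$x == 5], 15)

  band <- matrix(0, 50, 100); band[11:21, ] <- 255
  cvb <- extract_curve(band)
  expect_true(all(cvb$points$y == 15))
  expect_equal(sum(cvb$raster[16, ] == 255), 100)
  expect_equal(sum(cvb$raster == 255), 100)

  # varying-thickness band along a parabola: midline within 1 px everywhere
  par_y <- function(x) 35 - 0.012 * (x - 50)^2
  pm <- matrix(0, 50, 100)
  for (x in 0:99) {
    w <- 6 + 4 * (x %% 3)                  # thickness 6/10/14
    rows <- round(par_y(x) - w / 2):round(par_y(x) + w / 2)
    pm[rows + 1, x + 1] <- 255
  }
  cvp <- extract_curve(pm)
  expect_true(all(abs(cvp$points$y - par_y(cvp$points$x)) <= 1))

  expect_error(extract_curve(mask_from_pixels(10, 10, cbind(3, 3))), "degenerate")
})

test_that("curve length counts raster pixels of the polyline", {
  flat <- matrix(0, 50, 100); flat[26, 1:90] <- 255
  cv <- extract_curve(flat)
  expect_equal(eyebrow_length(cv), 90)

  diag_mask <- mask_from_pixels(60, 60, cbind(0:49, 0:49))
  cvd <- extract_curve(diag_mask)
  expect_equal(eyebrow_length(cvd), 50)     # 45-degree 8-connected line

  two <- mask_from_pixels(10, 10, rbind(c(2, 4), c(3, 4)))
  expect_equal(eyebrow_length(extract_curve(two)), 2)
})

test_that("average width is the exact area/length quotient", {
  expect_equal(average_width(900, 90), 10)
  expect_equal(average_width(1000, 80), 12.5)
  expect_error(average_width(100, 0), "length")
})

test_that("curvature equals the maximum endpoint-chord distance", {
  straight <- curve_from_points(0:20, rep(5, 21))
  expect_equal(eyebrow_curvature(straight), 0)

  expect_equal(eyebrow_curvature(curve_from_points(c(0, 1, 2), c(0, 1, 0))), 1)

  xx <- seq(0, 20, length.out = 201)
  semi <- curve_from_points(xx, -sqrt(pmax(100 - (xx - 10)^2, 0)))
  expect_equal(eyebrow_curvature(semi), 10, tolerance = 0.05)

  expect_error(eyebrow_curvature(curve_from_points(c(0, 1), c(0, 1))), "degenerate")

  # oracle equivalence on random curves
  set.seed(21)
  for (i in 1:100) {
    np <- sample(3:40, 1)
    pts_x <- sort(sample(0:99, np))
    pts_y <- runif(np, 0, 49)
    cv <- curve_from_points(pts_x, pts_y)
    expect_equal(eyebrow_curvature(cv), brute_curvature(cv$points),
                 tolerance = 1e-10)
  }
})

test_that("extracted curvature increases with generator apex height", {
  curv <- vapply(c(3, 6, 9, 12, 15), function(a) {
    eb <- gen_eyebrow(length = 85, width = 10, apex_height = a,
                      noise_blobs = 0, noise_sd = 0, seed = 1)
    eyebrow_features(eb$image)$curvature
  }, numeric(1))
  expect_true(all(diff(curv) > 0))
})

test_that("eyebrow descriptors are mutually consistent and bounded on the normalized frame", {
  eb <- gen_eyebrow(length = 85, width = 12, apex_height = 9, seed = 2)
  f <- eyebrow_features(eb$image)
  expect_lt(abs(f$length - 85) / 85, 0.10)
  expect_lt(abs(f$curvature - 9) / 9, 0.15)
  expect_equal(f$avg_width, f$area / f$length)
  expect_gte(f$area, f$length)

  fs <- eyebrow_features(gen_eyebrow(apex_height = 0, noise_blobs = 0,
                                     seed = 3)$image)
  expect_lte(fs$curvature, 1)

  expect_error(eyebrow_features(matrix(180, 50, 100)), "no eyebrow found")

  set.seed(14)
  for (i in 1:10) {
    eb <- gen_eyebrow(length = round(runif(1, 80, 90)),
                      width = round(runif(1, 11, 13)),
                      apex_height = runif(1, 1, 18), seed = i)
    f <- eyebrow_features(eb$image)
    expect_lte(f$length, 200)
    expect_lte(f$curvature, 50)
    expect_gte(f$area, f$length)
  }
})
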