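test_that("score banding uses left-closed bins with a closed final bin", {
  rec <- tibble::tibble(score = c(2.5, 3.0, 4.0, 5.0))
  b <- bin_by_score(rec)
  expect_equal(as.vector(table(b$band)[c("[2,3)", "[3,4)", "[4,5]")]),
               c(1L, 1L, 2L))
  expect_equal(as.character(b$band[b$score == 3.0]), "[3,4)")

  low <- bin_by_score(tibble::tibble(score = c(1.2, 2.2)))
  expect_equal(as.character(low$band), c("other", "[2,3)"))
  expect_error(bin_by_score(tibble::tibble(score = c(0.5, 3))), "\\[1, 5\\]")

  set.seed(2)
  sc <- tibble::tibble(score = runif(200, 1, 5))
  expect_equal(sum(table(bin_by_score(sc)$band)), 200L)
})

test_that("large-eye fractions use a strict threshold", {
  rec <- tibble::tibble(band = "[3,4)", eye_area = c(700, 850, 900, 500))
  expect_equal(fraction_large_eyes(rec)$fraction_large_eyes, 0.5)
  rec2 <- tibble::tibble(band = "[2,3)", eye_area = c(800, 799, 600))
  expect_equal(fraction_large_eyes(rec2)$fraction_large_eyes, 0)
})

test_that("planted cohort band fractions mirror the 24/46/56 percent structure", {
  fracs <- sapply(1:5, function(s) {
    fr <- fraction_large_eyes(gen_cohort(seed = s)$records)
    fr$fraction_large_eyes[match(c("[2,3)", "[3,4)", "[4,5]"), fr$band)]
  })
  avg <- rowMeans(fracs)
  expect_lt(abs(avg[1] - 0.24), 0.08)
  expect_lt(abs(avg[2] - 0.46), 0.08)
  expect_lt(abs(avg[3] - 0.56), 0.08)
  expect_true(all(diff(avg) > 0))
  fr42 <- fraction_large_eyes(gen_cohort(seed = 42)$records)
  expect_equal(fr42$n[match(c("[2,3)", "[3,4)", "[4,5]"), fr42$band)],
               c(92L, 146L, 62L))
})

test_that("the curvature/eye-area trend statistic behaves at the extremes", {
  rec <- tibble::tibble(band = "[4,5]", curvature = 1:10,
                        eye_area = seq(1000, 600, length.out = 10))
  tr <- curvature_eye_trend(rec)
  expect_equal(tr$spearman_rho, -1)
  expect_lt(tr$ols_slope, 0)

  co <- gen_cohort(n_per_band = c(0, 150, 0), rho_curv_eye = c(0, 0, 0), seed = 8)
  rec2 <- dplyr::mutate(co$records, band = "[3,4)")
  expect_lt(abs(curvature_eye_trend(rec2)$spearman_rho), 0.2)

  flat <- tibble::tibble(band = "[2,3)", curvature = rep(5, 6),
                         eye_area = runif(6, 600, 1000))
  trf <- curvature_eye_trend(flat)
  expect_identical(trf$flag, "constant-curvature")
  expect_true(is.na(trf$spearman_rho))
})

test_that("face-ratio means per curvature interval drop empty bins", {
  one <- tibble::tibble(band = "[4,5]", curvature = 7, face_ratio = 0.81)
  rb <- ratio_by_curvature_bins(one)
  expect_equal(nrow(rb), 1)
  expect_equal(rb$mean_ratio, 0.81)
  expect_equal(as.character(rb$curvature_bin), "[5,9)")

  same <- tibble::tibble(band = "x", curvature = c(2, 3, 10, 11),
                         face_ratio = rep(0.8, 4))
  rb2 <- ratio_by_curvature_bins(same)
  expect_equal(diff(rb2$mean_ratio), 0)
})

test_that("feature histograms conserve band counts", {
  rec <- tibble::tibble(band = "[3,4)", brow_length = rep(85, 10),
                        curvature = runif(10, 0, 24),
                        eye_area = runif(10, 500, 1100))
  h <- feature_histograms(rec)
  hl <- dplyr::filter(h, feature == "brow_length")
  expect_equal(hl$count[grepl("\\[80,90\\)", hl$bin)], 10L)
  sums <- dplyr::summarise(dplyr::group_by(h, feature), n = sum(count))
  expect_true(all(sums$n == 10))
})

test_that("planted cohort histograms peak in the reported modal intervals", {
  co <- gen_cohort(seed = 42)
  h <- feature_histograms(dplyr::mutate(co$records, band = factor(band)))
  modal <- function(f) {
    hf <- dplyr::filter(h, feature == f)
    hf <- dplyr::summarise(dplyr::group_by(hf, bin), n = sum(count))
    as.character(hf$bin[which.max(hf$n)])
  }
  expect_equal(modal("brow_length"), "[80,90)")
  expect_equal(modal("brow_area"), "[900,1100)")
  expect_equal(modal("brow_avg_width"), "[11,13)")
  expect_equal(modal("iris_ratio"), "[0.5,0.6)")
})

test_that("band reports are invariant to record order", {
  co <- gen_cohort(n_per_band = c(20, 20, 20), seed = 13)
  rec <- bin_by_score(co$records[, setdiff(names(co$records), "band")])
  set.seed(1)
  shuf <- rec[sample(nrow(rec)), ]
  r1 <- band_report(rec); r2 <- band_report(shuf)
  expect_equal(r1$band_sizes, r2$band_sizes)
  expect_equal(r1$large_eyes, r2$large_eyes)
  expect_equal(r1$trend, r2$trend)
  expect_equal(r1$ratio_by_curvature, r2$ratio_by_curvature)
})

test_that("the file pipeline round-trips a mini-cohort and tolerates gaps", {
  d <- withr::local_tempdir()
  co <- gen_cohort(n_per_band = c(2, 2, 2), seed = 7)
  cohort_write(co, d)
  res <- run_pipeline(file.path(d, "images"), file.path(d, "landmarks"),
                      file.path(d, "scores.csv"))
  expect_equal(nrow(res$features), 6)
  expect_true(all(res$features$errors == ""))
  expect_equal(sum(res$report$band_sizes$n), 6)
  expect_equal(res$features$face_ratio, co$records$face_ratio, tolerance = 1e-6)

  # image without a landmark file is flagged, the run continues
  file.remove(file.path(d, "landmarks", "img001.json"))
  res2 <- run_pipeline(file.path(d, "images"), file.path(d, "landmarks"))
  expect_equal(nrow(res2$features), 6)
  expect_match(res2$features$errors[res2$features$image_id == "img001"],
               "not found")

  expect_error(run_pipeline(withr::local_tempdir(), file.path(d, "landmarks")),
               "no images")
})
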