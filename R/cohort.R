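# Score-banded synthetic cohorts with planted associations, emulating the
# statistical structure of a 300-image scored face set: band sizes, eyebrow
# descriptor ranges (lengths 80-90 px, widths 11-13 px, curvature mostly
# 5-13 px), per-band eye-area distributions calibrated so the fraction of
# eyes above 800 px^2 is about 24%/46%/56% across bands, a per-band negative
# curvature/eye-area association, and a positive face-ratio-vs-curvature
# trend in the upper bands.

#' Generate a synthetic scored cohort with planted structure
#'
#' Samples per-record planted features (attractiveness score, eyebrow
#' geometry, eye geometry, face ratio) from a seeded Gaussian-copula model
#' and returns them as a truth table plus everything needed to materialize
#' each record's image fixtures ([cohort_extract()], [cohort_write()]).
#'
#' Per band, `(curvature, eye_area)` are drawn from a bivariate Gaussian
#' copula with rank correlation target `rho_curv_eye[band]`, transformed to
#' curvature `N(9, 4)` clipped to `[0.5, 22]` px and eye area
#' `N(eye_mu[band], eye_sd)` clipped to `[600, 1000]` px^2. The face ratio
#' follows `0.80 + slope_ratio_curv[band] * (curvature - 9)` plus `N(0,
#' 0.03)` noise, clipped to `[0.70, 0.92]`.
#'
#' @param n_per_band Record counts for the score bands `[2,3)`, `[3,4)`,
#'   `[4,5]`. Default `c(92, 146, 62)`.
#' @param rho_curv_eye Planted per-band Gaussian correlation between
#'   curvature and eye area. Default `c(-0.2, -0.4, -0.6)`.
#' @param slope_ratio_curv Planted per-band face-ratio slope per pixel of
#'   curvature. Default `c(0, 0.004, 0.006)`.
#' @param eye_mu,eye_sd Per-band eye-area means and common sd. Defaults
#'   `c(745, 792, 812)` and 80.
#' @param seed Integer seed. Default 42.
#' @return An object of class `cohort`: list with `records` (truth tibble,
#'   one row per record) and `params`.
#' @export
gen_cohort <- function(n_per_band = c(92, 146, 62),
                       rho_curv_eye = c(-0.2, -0.4, -0.6),
                       slope_ratio_curv = c(0, 0.004, 0.006),
                       eye_mu = c(745, 792, 812), eye_sd = 80,
                       seed = 42) {
  stopifnot(length(n_per_band) == 3L, all(n_per_band >= 0),
            all(abs(rho_curv_eye) <= 1))
  band_labels <- c("[2,3)", "[3,4)", "[4,5]")
  templates <- c("square", "oval", "round", "heart")
  records <- with_seed(seed, {
    purrr::map_dfr(1:3, function(b) {
      n <- n_per_band[b]
      if (n == 0L) return(tibble())
      rho <- rho_curv_eye[b]
      z1 <- rnorm(n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
      curvature <- pmin(pmax(9 + 4 * z1, 0.5), 22)
      eye_area <- pmin(pmax(eye_mu[b] + eye_sd * z2, 600), 1000)
      iris_ratio <- pmin(pmax(rnorm(n, 0.55, 0.03), 0.45), 0.65)
      face_ratio <- pmin(pmax(0.80 + slope_ratio_curv[b] * (curvature - 9) +
                                rnorm(n, 0, 0.03), 0.70), 0.92)
      tibble(
        band = band_labels[b],
        score = runif(n, 2 + (b - 1), 3 + (b - 1) - if (b == 3) 1e-9 else 0),
        curvature = curvature,
        brow_length = round(runif(n, 80, 90)),
        brow_width = round(runif(n, 11, 13)),
        eye_area = eye_area,
        iris_ratio = iris_ratio,
        face_ratio = face_ratio,
        face_template = sample(templates, n, replace = TRUE))
    })
  })
  records <- dplyr::mutate(
    records,
    image_id = sprintf("img%03d", dplyr::row_number()),
    brow_area = .data$brow_length * .data$brow_width,
    brow_avg_width = .data$brow_width,
    iris_area = .data$iris_ratio * .data$eye_area,
    D1 = 170, D2 = 170 / .data$face_ratio,
    record_seed = (abs(seed) + 7919L * dplyr::row_number()) %% 2147483629L)
  records <- dplyr::relocate(records, "image_id")
  structure(list(records = records,
                 params = list(n_per_band = n_per_band,
                               rho_curv_eye = rho_curv_eye,
                               slope_ratio_curv = slope_ratio_curv,
                               eye_mu = eye_mu, eye_sd = eye_sd, seed = seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$records), " records, bands ",
      paste(table(x$records$band), collapse = "/"),
      ", seed ", x$params$seed, "\n", sep = "")
  invisible(x)
}

# internal: generator inputs for one truth record
record_specs <- function(rec) {
  mn <- rec$eye_area / pi
  R <- sqrt(rec$iris_ratio * mn)
  aspect <- min(2.2, max(1.05, 0.9 * mn / (R + 1.5)^2))
  n <- sqrt(mn / aspect)
  m <- mn / n
  list(
    eyebrow = list(length = rec$brow_length, width = rec$brow_width,
                   apex_height = rec$curvature, seed = rec$record_seed),
    eye = list(center = c(50, 25), semi_axes = c(m, n),
               iris_radius = R, seed = rec$record_seed + 1),
    face = list(template = rec$face_template, target_ratio = rec$face_ratio))
}

#' Render and re-extract planted records of a cohort
#'
#' Materializes each selected record's eyebrow patch, eye patch and
#' landmark set with the planted parameters and runs the extraction
#' pipeline on them, returning extracted features side by side with the
#' planted truth (truth columns prefixed `true_`). This is the round-trip
#' used to validate the whole pipeline at desk scale.
#'
#' @param cohort A [gen_cohort()] object.
#' @param bands Optional subset of band labels to materialize.
#' @param parts Which parts to extract, subset of
#'   `c("eyebrow", "eye", "face")`.
#' @return A tibble with one row per record: identifiers, score, extracted
#'   features and `true_*` columns.
#' @export
cohort_extract <- function(cohort, bands = NULL,
                           parts = c("eyebrow", "eye", "face")) {
  stopifnot(inherits(cohort, "cohort"))
  recs <- cohort$records
  if (!is.null(bands)) recs <- dplyr::filter(recs, .data$band %in% bands)
  purrr::map_dfr(seq_len(nrow(recs)), function(i) {
    rec <- recs[i, ]
    sp <- record_specs(rec)
    out <- tibble(image_id = rec$image_id, band = rec$band, score = rec$score)
    if ("eyebrow" %in% parts) {
      eb <- gen_eyebrow(length = sp$eyebrow$length, width = sp$eyebrow$width,
                        apex_height = sp$eyebrow$apex_height,
                        seed = sp$eyebrow$seed)
      feats <- tryCatch(eyebrow_features(eb$image, patch_id = rec$image_id),
                        error = function(e) tibble(area = NA_real_, length = NA_real_,
                                                   avg_width = NA_real_, curvature = NA_real_))
      out <- dplyr::bind_cols(out, dplyr::rename(feats, brow_area = "area",
                                                 brow_length = "length",
                                                 brow_avg_width = "avg_width"))
    }
    if ("eye" %in% parts) {
      ey <- gen_eye(semi_axes = sp$eye$semi_axes, iris_radius = sp$eye$iris_radius,
                    seed = sp$eye$seed)
      ef <- tryCatch(eye_features(ey$image),
                     error = function(e) tibble(eye_area = NA_real_, iris_area = NA_real_,
                                                iris_ratio = NA_real_, fit_flags = "failed"))
      out <- dplyr::bind_cols(out, ef)
    }
    if ("face" %in% parts) {
      fc <- gen_face_landmarks(sp$face$template, target_ratio = sp$face$target_ratio)
      fr <- face_ratio(fc$landmarks)
      out <- dplyr::bind_cols(out, dplyr::rename(fr, face_ratio = "ratio",
                                                 face_flag = "flag"))
    }
    truth <- dplyr::select(rec, true_curvature = "curvature",
                           true_brow_length = "brow_length",
                           true_brow_width = "brow_width",
                           true_brow_area = "brow_area",
                           true_eye_area = "eye_area",
                           true_iris_ratio = "iris_ratio",
                           true_face_ratio = "face_ratio")
    dplyr::bind_cols(out, truth)
  })
}

#' Write cohort fixtures to disk
#'
#' Materializes each selected record as a composite flat-shaded face image
#' (eyebrow patches and eye patches pasted into the landmark-defined
#' regions at unit scale, dark hair cap for the hairline detector) plus a
#' landmark JSON, and writes `scores.csv` (image_id, score) and
#' `truth.csv` (all planted parameters).
#'
#' @param cohort A [gen_cohort()] object.
#' @param dir Output directory (created if needed); images go to
#'   `dir/images`, landmarks to `dir/landmarks`.
#' @param bands Optional subset of band labels.
#' @return `dir`, invisibly.
#' @export
cohort_write <- function(cohort, dir, bands = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  recs <- cohort$records
  if (!is.null(bands)) recs <- dplyr::filter(recs, .data$band %in% bands)
  img_dir <- file.path(dir, "images"); lm_dir <- file.path(dir, "landmarks")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lm_dir, recursive = TRUE, showWarnings = FALSE)
  lay <- face_layout()
  for (i in seq_len(nrow(recs))) {
    rec <- recs[i, ]
    sp <- record_specs(rec)
    fc <- gen_face_landmarks(sp$face$template, target_ratio = sp$face$target_ratio)
    canvas <- fc$image
    eb <- gen_eyebrow(length = sp$eyebrow$length, width = sp$eyebrow$width,
                      apex_height = sp$eyebrow$apex_height, seed = sp$eyebrow$seed)
    ey <- gen_eye(semi_axes = sp$eye$semi_axes, iris_radius = sp$eye$iris_radius,
                  seed = sp$eye$seed)
    paste_patch <- function(canvas, patch, origin) {
      rows <- origin[2L] + seq_len(nrow(patch))
      cols <- origin[1L] + seq_len(ncol(patch))
      canvas[rows, cols] <- patch
      canvas
    }
    canvas <- paste_patch(canvas, eb$image, lay$brow_left)
    canvas <- paste_patch(canvas, eb$image[, ncol(eb$image):1], lay$brow_right)
    canvas <- paste_patch(canvas, ey$image, lay$eye_left)
    canvas <- paste_patch(canvas, ey$image[, ncol(ey$image):1], lay$eye_right)
    write_gray(canvas, file.path(img_dir, paste0(rec$image_id, ".png")))
    write_landmarks(fc$landmarks, file.path(lm_dir, paste0(rec$image_id, ".json")))
  }
  readr::write_csv(dplyr::select(recs, "image_id", "score"),
                   file.path(dir, "scores.csv"))
  readr::write_csv(recs, file.path(dir, "truth.csv"))
  invisible(dir)
}
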