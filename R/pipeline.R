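# End-to-end pipeline: per-image feature extraction from an image directory
# plus landmark files, followed by the banded cohort report.

#' Extract all geometric features of one face image
#'
#' Crops the eyebrow and eye regions from the landmark-defined bounding
#' boxes (brow landmarks 17-21 / 22-26, eye landmarks 36-41 / 42-47, each
#' padded), normalizes them to the working size, runs the eyebrow and eye
#' models on both sides, and computes the face ratio (hairline from the
#' landmark file when present, otherwise detected, otherwise the fallback
#' point).
#'
#' @param image Grayscale face image matrix.
#' @param landmarks A [landmark_set()].
#' @param image_id Identifier used in output rows and error messages.
#' @param config Optional named list overriding defaults: `size`
#'   (`c(100, 50)`), `brow_pad` (`c(4, 10)`), `eye_pad` (`c(10, 15)`),
#'   `window`, `offset`, `min_blob`, `magnitude_threshold`, `iris_factor`,
#'   plus [detect_hairline()] settings under `hairline`.
#' @return A one-row tibble with per-side eyebrow features
#'   (`brow_<feature>_left/right`), per-side eye features, side means
#'   (`curvature`, `brow_length`, `brow_area`, `brow_avg_width`,
#'   `eye_area`, `iris_area`, `iris_ratio`), face columns (`D1`, `D2`,
#'   `face_ratio`, `hairline_source`) and an `errors` string (empty when
#'   every stage succeeded).
#' @export
extract_face_features <- function(image, landmarks, image_id = "image",
                                  config = list()) {
  cfg <- utils::modifyList(list(size = c(100, 50), brow_pad = c(4, 10),
                                eye_pad = c(10, 15), window = 15, offset = 6,
                                min_blob = 30, magnitude_threshold = 0.25,
                                iris_factor = 0.9, hairline = list()),
                           config)
  errors <- character()
  grab <- function(idx, pad) {
    pts <- lm_pt(landmarks, idx)
    x0 <- max(0, floor(min(pts[, 1]) - pad[1]))
    y0 <- max(0, floor(min(pts[, 2]) - pad[2]))
    x1 <- min(ncol(image) - 1, ceiling(max(pts[, 1]) + pad[1]))
    y1 <- min(nrow(image) - 1, ceiling(max(pts[, 2]) + pad[2]))
    normalize_roi(image, c(x0, y0, x1 - x0 + 1, y1 - y0 + 1), cfg$size)
  }
  brow_one <- function(idx, side) {
    feats <- tryCatch(
      eyebrow_features(grab(idx, cfg$brow_pad), cfg$window, cfg$offset,
                       cfg$min_blob, patch_id = paste0(image_id, ":", side)),
      error = function(e) {
        errors <<- c(errors, paste0("eyebrow-", side, ": ", conditionMessage(e)))
        tibble(area = NA_real_, length = NA_real_, avg_width = NA_real_,
               curvature = NA_real_)
      })
    setNames(feats, paste0("brow_", c("area", "length", "avg_width", "curvature"),
                           "_", side))
  }
  eye_one <- function(idx, side) {
    feats <- tryCatch(
      eye_features(grab(idx, cfg$eye_pad), cfg$magnitude_threshold,
                   cfg$iris_factor),
      error = function(e) {
        errors <<- c(errors, paste0("eye-", side, ": ", conditionMessage(e)))
        tibble(eye_area = NA_real_, iris_area = NA_real_, iris_ratio = NA_real_,
               fit_flags = "failed")
      })
    setNames(feats, paste0(c("eye_area", "iris_area", "iris_ratio", "fit_flags"),
                           "_", side))
  }
  row <- dplyr::bind_cols(
    tibble(image_id = image_id),
    brow_one(17:21, "left"), brow_one(22:26, "right"),
    eye_one(36:41, "left"), eye_one(42:47, "right"))

  face <- tryCatch({
    hl <- if (!is.null(landmarks$hairline)) {
      tibble(x = landmarks$hairline[1], y = landmarks$hairline[2], source = "file")
    } else {
      do.call(detect_hairline, c(list(image, landmarks), cfg$hairline))
    }
    fr <- face_ratio(landmarks, hairline = hl)
    tibble(D1 = fr$D1, D2 = fr$D2, face_ratio = fr$ratio,
           hairline_source = hl$source)
  }, error = function(e) {
    errors <<- c(errors, paste0("face: ", conditionMessage(e)))
    tibble(D1 = NA_real_, D2 = NA_real_, face_ratio = NA_real_,
           hairline_source = NA_character_)
  })

  side_mean <- function(a, b) ifelse(is.na(a) & is.na(b), NA_real_,
                                     rowMeans(cbind(a, b), na.rm = TRUE))
  dplyr::bind_cols(row, face, tibble(
    curvature = side_mean(row$brow_curvature_left, row$brow_curvature_right),
    brow_length = side_mean(row$brow_length_left, row$brow_length_right),
    brow_area = side_mean(row$brow_area_left, row$brow_area_right),
    brow_avg_width = side_mean(row$brow_avg_width_left, row$brow_avg_width_right),
    eye_area = side_mean(row$eye_area_left, row$eye_area_right),
    iris_area = side_mean(row$iris_area_left, row$iris_area_right),
    iris_ratio = side_mean(row$iris_ratio_left, row$iris_ratio_right),
    errors = paste(errors, collapse = "; ")))
}

#' Run the extraction and analysis pipeline over directories
#'
#' Extracts features for every image in `image_dir` (PNG/JPEG), pairing
#' each with `landmark_dir/<image_id>.json`; images without a landmark
#' file are flagged and skipped, and per-stage failures are captured in
#' the `errors` column without stopping the run. With a scores table the
#' banded report is computed as well.
#'
#' @param image_dir Directory of face images.
#' @param landmark_dir Directory of landmark JSON files.
#' @param scores Optional path to a `scores.csv` (`image_id`, `score`) or
#'   a data frame; without it only extraction runs.
#' @param out_dir Optional output directory for `features.csv` and
#'   `report.json`.
#' @param config Passed to [extract_face_features()].
#' @param max_fail_frac Error out if more than this fraction of images
#'   fail completely. Default 0.5.
#' @return A list with `features` (tibble) and `report` (list of tibbles,
#'   `NULL` without scores), invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(image_dir, landmark_dir, scores = NULL,
                         out_dir = NULL, config = list(),
                         max_fail_frac = 0.5) {
  paths <- sort(list.files(image_dir, pattern = "\\.(png|jpg|jpeg|bmp)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(paths) == 0L) abort(paste0("no images found in ", image_dir))
  features <- purrr::map_dfr(paths, function(p) {
    id <- sub("\\.[^.]+$", "", basename(p))
    lm_path <- file.path(landmark_dir, paste0(id, ".json"))
    if (!file.exists(lm_path)) {
      return(tibble(image_id = id, errors = "landmarks: file not found"))
    }
    img <- load_gray(p)
    lms <- read_landmarks(lm_path)
    extract_face_features(img, lms, image_id = id, config = config)
  })
  failed <- is.na(features$curvature %||% NA) & is.na(features$eye_area %||% NA)
  if (mean(failed) > max_fail_frac) {
    abort(sprintf("pipeline failed on %d of %d images", sum(failed), nrow(features)))
  }
  report <- NULL
  if (!is.null(scores)) {
    sc <- if (is.data.frame(scores)) as_tibble(scores)
          else readr::read_csv(scores, show_col_types = FALSE)
    if (!all(c("image_id", "score") %in% names(sc))) {
      abort("scores must have columns image_id and score")
    }
    merged <- dplyr::inner_join(features, sc, by = "image_id")
    report <- band_report(bin_by_score(merged))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(features, file.path(out_dir, "features.csv"))
    if (!is.null(report)) {
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           dataframe = "rows", factor = "string", digits = NA,
                           pretty = TRUE)
    }
    return(invisible(list(features = features, report = report)))
  }
  list(features = features, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
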