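# Face-shape model: 68-point landmark handling, hairline detection, and the
# facial transverse/longitudinal ratio D1/D2.

#' Construct a landmark set
#'
#' @param points A 68 x 2 matrix (or data frame) of `x`, `y` landmark
#'   coordinates following the standard 68-point annotation (jaw 0-16,
#'   brows 17-26, nose 27-35, eyes 36-47, mouth 48-67), 0-based pixel
#'   coordinates.
#' @param hairline Optional `c(x, y)` hairline point.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, hairline = NULL) {
  points <- as.matrix(points)
  if (nrow(points) != 68L || ncol(points) != 2L) {
    abort(sprintf("expected 68 landmark points with x and y, got %d x %d",
                  nrow(points), ncol(points)))
  }
  storage.mode(points) <- "double"
  if (anyNA(points) || any(!is.finite(points))) abort("landmark coordinates must be finite")
  dimnames(points) <- list(NULL, c("x", "y"))
  if (!is.null(hairline)) {
    hairline <- as.numeric(hairline)
    if (length(hairline) != 2L || anyNA(hairline)) abort("hairline must be c(x, y)")
  }
  structure(list(points = points, hairline = hairline), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> 68 points; hairline ",
      if (is.null(x$hairline)) "absent" else sprintf("(%.1f, %.1f)", x$hairline[1], x$hairline[2]),
      "\n", sep = "")
  invisible(x)
}

# internal: landmark point(s) by 0-based index
lm_pt <- function(landmarks, i) {
  landmarks$points[i + 1L, , drop = length(i) == 1L]
}

#' Read a 68-point landmark file
#'
#' Reads the JSON schema `{"points": [[x, y], ... 68 entries],
#' "hairline": [x, y]}` (hairline optional).
#'
#' @param path Path to a landmark JSON file.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read landmark file: ", path))
  dat <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) abort(paste0("malformed landmark file ", path,
                                                   ": ", conditionMessage(e))))
  if (is.null(dat$points)) abort(paste0("landmark file ", path, ": missing 'points'"))
  pts <- dat$points
  if (is.list(pts)) pts <- do.call(rbind, pts)
  if (!is.matrix(pts) || nrow(pts) != 68L || ncol(pts) != 2L) {
    abort(sprintf("landmark file %s: 'points' expected 68 [x, y] pairs, got %s",
                  path, paste(dim(as.matrix(pts)), collapse = " x ")))
  }
  landmark_set(pts, hairline = dat$hairline)
}

#' Write a landmark set to JSON
#'
#' @param landmarks A [landmark_set()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  obj <- list(points = unname(apply(landmarks$points, 1L, identity, simplify = FALSE)))
  if (!is.null(landmarks$hairline)) obj$hairline <- landmarks$hairline
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Detect the hairline point above the brows
#'
#' Scans upward from the brow line along the vertical through the
#' nose-bridge landmark (index 27) and returns the first pixel, moving up,
#' where the local vertical intensity gradient exceeds `grad_threshold` for
#' `k` consecutive rows (the skin-to-hair transition). The gradient is a
#' central difference averaged over a small column band for robustness.
#' When no transition is found and `fallback = TRUE`, a point offset above
#' the brow line by `fallback_factor` times the eyes-to-chin distance is
#' returned and flagged.
#'
#' @param image Grayscale face image.
#' @param landmarks A [landmark_set()].
#' @param grad_threshold Gradient magnitude threshold (intensity units per
#'   row). Default 30.
#' @param k Consecutive rows required above threshold. Default 2.
#' @param halfwidth Column half-band averaged over. Default 2.
#' @param fallback Use the offset fallback when no transition is found?
#'   Default `TRUE`.
#' @param fallback_factor Offset as a fraction of the eyes-to-chin
#'   distance. Default 0.6.
#' @return One-row tibble `x`, `y`, `source` (`"detected"` or
#'   `"fallback"`).
#' @export
detect_hairline <- function(image, landmarks, grad_threshold = 30, k = 2,
                            halfwidth = 2, fallback = TRUE,
                            fallback_factor = 0.6) {
  check_gray(image)
  stopifnot(inherits(landmarks, "landmark_set"))
  nose_x <- lm_pt(landmarks, 27L)[1L]
  brow_y <- mean(lm_pt(landmarks, 17:26)[, 2L])
  cols <- round(nose_x) + seq(-halfwidth, halfwidth)
  cols <- cols[cols >= 0 & cols < ncol(image)] + 1L
  if (length(cols) == 0L) abort("hairline not found: scan column outside image")
  y0 <- min(max(floor(brow_y), 1), nrow(image) - 2)
  run <- 0L
  for (y in seq(y0, 1L)) {
    lo <- max(y - 1L, 0L); hi <- min(y + 1L, nrow(image) - 1L)
    g <- abs(mean(image[lo + 1L, cols]) - mean(image[hi + 1L, cols])) / (hi - lo)
    if (g > grad_threshold) {
      run <- run + 1L
      if (run >= k) return(tibble(x = nose_x, y = y + (k - 1L), source = "detected"))
    } else run <- 0L
  }
  if (fallback) {
    eyes_y <- mean(lm_pt(landmarks, 36:47)[, 2L])
    chin <- lm_pt(landmarks, 8L)
    dist_ec <- sqrt(sum((c(nose_x, eyes_y) - chin)^2))
    return(tibble(x = nose_x, y = brow_y - fallback_factor * dist_ec,
                  source = "fallback"))
  }
  abort("hairline not found and fallback disabled")
}

#' Facial transverse/longitudinal ratio D1/D2
#'
#' `D1` is the face width: the longest chord among the opposing jaw-contour
#' landmark pairs `(i, 16 - i)`, `i = 0..5` (or a fixed pair). `D2` is the
#' face height: the distance from the hairline point to the chin landmark
#' (index 8). Ratios near 1 indicate round faces, smaller ratios longer
#' faces; values outside `(0.4, 1.3)` are flagged.
#'
#' @param landmarks A [landmark_set()] carrying a hairline point, or pass
#'   `hairline` explicitly (e.g. a [detect_hairline()] result).
#' @param hairline Optional `c(x, y)` or one-row data frame with `x`, `y`
#'   overriding `landmarks$hairline`.
#' @param d1_pair `"max"` (default) or a fixed pair of 0-based jaw indices
#'   such as `c(0, 16)`.
#' @return One-row tibble `D1`, `D2`, `ratio`, `flag` (`"ok"` or
#'   `"ratio-implausible"`).
#' @export
face_ratio <- function(landmarks, hairline = NULL, d1_pair = "max") {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (is.null(hairline)) hairline <- landmarks$hairline
  if (is.data.frame(hairline)) hairline <- c(hairline$x[1L], hairline$y[1L])
  if (is.null(hairline)) {
    abort("missing hairline point: supply one or run detect_hairline() first")
  }
  if (identical(d1_pair, "max")) {
    spans <- vapply(0:5, function(i) {
      sqrt(sum((lm_pt(landmarks, i) - lm_pt(landmarks, 16L - i))^2))
    }, numeric(1))
    D1 <- max(spans)
  } else {
    D1 <- sqrt(sum((lm_pt(landmarks, d1_pair[1L]) - lm_pt(landmarks, d1_pair[2L]))^2))
  }
  chin <- lm_pt(landmarks, 8L)
  D2 <- sqrt(sum((as.numeric(hairline) - chin)^2))
  if (D2 <= 0) abort("degenerate face height: hairline coincides with chin")
  ratio <- D1 / D2
  tibble(D1 = D1, D2 = D2, ratio = ratio,
         flag = if (ratio > 0.4 && ratio < 1.3) "ok" else "ratio-implausible")
}
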