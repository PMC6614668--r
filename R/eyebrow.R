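# Eyebrow model: adaptive mean thresholding of the normalized 100x50 patch,
# blob denoising, the per-column midline curve, and the four descriptors
# (area, length, average width, curvature).

#' Adaptive mean thresholding
#'
#' Binarizes an image against a per-pixel threshold `T = mean(neighborhood) -
#' offset`, the neighborhood being a square `window x window` box around each
#' pixel (replicate padding at the borders). With
#' `polarity = "dark-foreground"` (the default used for eyebrows, which are
#' darker than skin) pixels with `gray < T` become foreground 255; with
#' `"bright-foreground"` pixels with `gray >= T` become 255.
#'
#' @param image Grayscale matrix.
#' @param window Odd neighborhood side length in pixels, `>= 3`. Default 15.
#' @param offset Constant subtracted from the neighborhood mean. Default 6
#'   (large enough that background noise does not cross the threshold).
#' @param polarity `"dark-foreground"` or `"bright-foreground"`.
#' @return Binary mask matrix with values `{0, 255}`.
#' @export
adaptive_threshold <- function(image, window = 15, offset = 6,
                               polarity = c("dark-foreground", "bright-foreground")) {
  check_gray(image)
  polarity <- match.arg(polarity)
  if (window %% 2 == 0 || window < 3) abort("window must be odd and >= 3")
  T <- box_mean(image, as.integer(window)) - offset
  fg <- if (polarity == "dark-foreground") image < T else image >= T
  out <- matrix(0, nrow(image), ncol(image))
  out[fg] <- 255
  out
}

#' Segment the eyebrow in a normalized patch
#'
#' Adaptive dark-foreground thresholding followed by blob denoising; all
#' surviving components are kept (an eyebrow can break into segments under
#' sparse hair).
#'
#' @param patch Normalized grayscale patch (typically 100 x 50).
#' @param window,offset Thresholding parameters, see [adaptive_threshold()].
#' @param min_blob Minimum component size kept, in pixels. Default 30.
#' @param patch_id Optional identifier used in error messages.
#' @return Binary mask of the eyebrow.
#' @export
segment_eyebrow <- function(patch, window = 15, offset = 6, min_blob = 30,
                            patch_id = NULL) {
  mask <- adaptive_threshold(patch, window, offset, "dark-foreground")
  mask <- blob_denoise(mask, min_blob)
  if (!any(mask > 0)) {
    abort(paste0("no eyebrow found",
                 if (!is.null(patch_id)) paste0(" in patch ", patch_id)))
  }
  mask
}

#' Eyebrow area
#'
#' The number of foreground (white) pixels in the segmented eyebrow mask.
#'
#' @param mask Binary mask.
#' @return Pixel count.
#' @export
eyebrow_area <- function(mask) {
  check_mask(mask)
  sum(mask == 255)
}

#' Extract the eyebrow midline curve
#'
#' For every column carrying foreground, takes the midpoint of the minimum
#' and maximum foreground rows (ties at .5 rounded down), then connects
#' consecutive column points with 8-connected line segments into a raster
#' polyline.
#'
#' @param mask Binary eyebrow mask.
#' @return An object of class `eyebrow_curve`: a list with `points` (a tibble
#'   of 0-based `x`, `y` midline points, one per foreground column) and
#'   `raster` (the `{0,255}` polyline mask).
#' @export
extract_curve <- function(mask) {
  check_mask(mask)
  cols <- which(apply(mask > 0, 2L, any))
  if (length(cols) < 2L) abort("degenerate eyebrow: fewer than 2 foreground columns")
  ys <- vapply(cols, function(j) {
    rows <- which(mask[, j] > 0)
    floor((min(rows) - 1 + max(rows) - 1) / 2)
  }, numeric(1))
  pts <- tibble(x = cols - 1, y = ys)
  raster <- matrix(0, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(pts) - 1L)) {
    seg <- bresenham(pts$x[k], pts$y[k], pts$x[k + 1L], pts$y[k + 1L])
    raster[cbind(seg[, 2L] + 1L, seg[, 1L] + 1L)] <- 255
  }
  structure(list(points = pts, raster = raster), class = "eyebrow_curve")
}

#' @export
print.eyebrow_curve <- function(x, ...) {
  cat("<eyebrow_curve> ", nrow(x$points), " column points, raster length ",
      sum(x$raster == 255), " px\n", sep = "")
  invisible(x)
}

#' Eyebrow length
#'
#' The number of white pixels in the rasterized midline polyline.
#'
#' @param curve An [extract_curve()] result.
#' @return Pixel count `L`.
#' @export
eyebrow_length <- function(curve) {
  stopifnot(inherits(curve, "eyebrow_curve"))
  sum(curve$raster == 255)
}

#' Average eyebrow width
#'
#' Eyebrow area divided by eyebrow length (exact quotient, not rounded).
#'
#' @param area Foreground pixel count.
#' @param length Curve length in pixels, `>= 1`.
#' @return Average width in pixels.
#' @export
average_width <- function(area, length) {
  if (length < 1) abort("length must be >= 1")
  area / length
}

#' Eyebrow curvature (bending degree)
#'
#' Fits the straight line through the two endpoint curve points and returns
#' the maximum perpendicular distance from the interior curve points to that
#' line (endpoints excluded) — a sagitta-like measure of how bent the
#' eyebrow is, in pixels.
#'
#' @param curve An [extract_curve()] result (at least 3 column points).
#' @return Curvature in pixels, `>= 0`.
#' @export
eyebrow_curvature <- function(curve) {
  stopifnot(inherits(curve, "eyebrow_curve"))
  pts <- curve$points
  n <- nrow(pts)
  if (n < 3L) abort("degenerate eyebrow: fewer than 3 curve points")
  line <- endpoint_line(c(pts$x[1L], pts$y[1L]), c(pts$x[n], pts$y[n]))
  interior <- pts[-c(1L, n), ]
  max(abs(line[1L] * interior$x + line[2L] * interior$y + line[3L]) /
        sqrt(line[1L]^2 + line[2L]^2))
}

#' Eyebrow shape descriptors for a normalized patch
#'
#' Runs segmentation, midline extraction and the four descriptors on a
#' normalized eyebrow patch.
#'
#' @inheritParams segment_eyebrow
#' @return A one-row tibble: `area`, `length`, `avg_width`, `curvature`
#'   (all in pixels of the normalized frame).
#' @export
eyebrow_features <- function(patch, window = 15, offset = 6, min_blob = 30,
                             patch_id = NULL) {
  mask <- segment_eyebrow(patch, window, offset, min_blob, patch_id)
  curve <- extract_curve(mask)
  area <- eyebrow_area(mask)
  len <- eyebrow_length(curve)
  tibble(area = area, length = len,
         avg_width = average_width(area, len),
         curvature = eyebrow_curvature(curve))
}

# internal: line A x + B y + C = 0 through two points; vertical when the
# endpoints share a column
endpoint_line <- function(p1, p2) {
  if (all(p1 == p2)) abort("degenerate line: coincident endpoints")
  A <- p2[2L] - p1[2L]
  B <- p1[1L] - p2[1L]
  C <- p2[1L] * p1[2L] - p1[1L] * p2[2L]
  if (A == 0 && B == 0) abort("degenerate line: coincident endpoints")
  c(A, B, C)
}

# internal: 8-connected Bresenham segment, inclusive endpoints,
# columns of the result are 0-based (x, y)
bresenham <- function(x0, y0, x1, y1) {
  x0 <- as.integer(round(x0)); y0 <- as.integer(round(y0))
  x1 <- as.integer(round(x1)); y1 <- as.integer(round(y1))
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  n <- max(dx, -dy) + 1L
  out <- matrix(0L, n, 2L)
  for (i in seq_len(n)) {
    out[i, ] <- c(x0, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  out[seq_len(i), , drop = FALSE]
}
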