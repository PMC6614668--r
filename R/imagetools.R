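# Shared raster primitives. Images are numeric matrices, rows = y, cols = x,
# 0-based pixel coordinates in all user-facing point sets.

#' Load an image as a grayscale intensity matrix
#'
#' Reads a PNG/JPEG/BMP/TIFF file and returns a numeric matrix with values in
#' `[0, 255]`, rows indexing `y` (top to bottom) and columns indexing `x`.
#' RGB inputs are converted to luminance with the ITU-R BT.601 weights
#' `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param path Path to a readable image file.
#' @return A `height x width` numeric matrix of intensities in `[0, 255]`.
#' @export
load_gray <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(paste0("cannot read image file: ", path))
  }
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) abort(paste0("cannot read image file: ", path,
                                                   " (", conditionMessage(e), ")")))
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) {
    nch <- dim(dat)[3L]
    dat <- if (nch >= 3L) {
      0.299 * dat[, , 1L] + 0.587 * dat[, , 2L] + 0.114 * dat[, , 3L]
    } else {
      dat[, , 1L]
    }
  }
  # EBImage stores (x, y) in [0,1]; transpose to rows = y and rescale
  m <- t(dat) * 255
  m[m < 0] <- 0; m[m > 255] <- 255
  unname(m)
}

#' Write a binary mask as a PNG file
#'
#' @param mask Binary mask matrix (values `{0, 255}`).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  EBImage::writeImage(EBImage::Image(t(mask) / 255), path, type = "png")
  invisible(path)
}

#' Write a grayscale image as a PNG file
#'
#' @param image Intensity matrix in `[0, 255]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_gray <- function(image, path) {
  check_gray(image)
  EBImage::writeImage(EBImage::Image(t(image) / 255), path, type = "png")
  invisible(path)
}

#' Crop a region of interest and resample it to a fixed size
#'
#' Crops `bbox` from `image` and resamples it bilinearly to the target
#' dimensions (the normalization step applied to eyebrow and eye regions
#' before feature extraction, by default to 100 x 50). When the bbox already
#' has the target size the crop is returned pixel-identically.
#'
#' @param image Grayscale matrix.
#' @param bbox Rectangle `c(x, y, width, height)` in 0-based source pixels.
#' @param target Output size `c(width, height)`, default `c(100, 50)`.
#' @return A `target[2] x target[1]` intensity matrix.
#' @export
normalize_roi <- function(image, bbox, target = c(100, 50)) {
  check_gray(image)
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4L) abort("bbox must be c(x, y, width, height)")
  x0 <- bbox[1L]; y0 <- bbox[2L]; bw <- bbox[3L]; bh <- bbox[4L]
  if (bw < 1 || bh < 1) abort("zero-area bbox")
  if (x0 < 0 || y0 < 0 || x0 + bw > ncol(image) || y0 + bh > nrow(image)) {
    abort("bbox outside image bounds")
  }
  if (any(target < 1)) abort("target dimensions must be >= 1")
  crop <- image[(y0 + 1):(y0 + bh), (x0 + 1):(x0 + bw), drop = FALSE]
  if (bw == target[1L] && bh == target[2L]) return(crop)
  r <- EBImage::resize(EBImage::Image(t(crop) / 255),
                       w = target[1L], h = target[2L], filter = "bilinear")
  out <- t(EBImage::imageData(r)) * 255
  out[out < 0] <- 0; out[out > 255] <- 255
  unname(out)
}

# internal: integer label matrix, 0 = background. 4-connectivity comes from
# EBImage::bwlabel; 8-connectivity merges 4-labels across diagonal adjacencies
# with a small union-find.
label_components <- function(mask, connectivity = 8) {
  check_mask(mask)
  if (!connectivity %in% c(4, 8)) abort("connectivity must be 4 or 8")
  lab <- EBImage::imageData(EBImage::bwlabel(mask > 0))
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (connectivity == 4 || nlab <= 1L) return(lab)

  # diagonal label pairs
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]     # down-right
  c_ <- lab[-nr, -1]; d <- lab[-1, -nc]    # down-left
  keep1 <- a > 0L & b > 0L & a != b
  keep2 <- c_ > 0L & d > 0L & c_ != d
  pairs <- rbind(cbind(a[keep1], b[keep1]), cbind(c_[keep2], d[keep2]))
  if (nrow(pairs) == 0L) return(lab)

  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  fg <- lab > 0L
  lab[fg] <- relab[lab[fg]]
  lab
}

#' Connected components of a binary mask
#'
#' @param mask Binary mask matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return A tibble with one row per component: `component`, `size`, and
#'   `pixels`, a list-column of two-column matrices of 0-based `(x, y)`
#'   pixel coordinates. Empty masks give a zero-row tibble.
#' @export
connected_components <- function(mask, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  nlab <- max(lab)
  if (nlab == 0L) {
    return(tibble(component = integer(), size = integer(), pixels = list()))
  }
  idx <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[lab > 0L]
  pts <- cbind(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L)
  pix <- lapply(split(seq_along(labs), labs), function(i) pts[i, , drop = FALSE])
  tibble(component = seq_len(nlab),
         size = vapply(pix, nrow, integer(1), USE.NAMES = FALSE),
         pixels = unname(pix))
}

#' Remove small foreground blobs from a binary mask
#'
#' Deletes every 8-connected (or 4-connected) foreground component with fewer
#' than `min_area` pixels; surviving components are kept pixel-exactly.
#'
#' @param mask Binary mask matrix.
#' @param min_area Minimum component size kept (inclusive), `>= 1`.
#' @param connectivity 4 or 8 (default 8).
#' @return The denoised mask.
#' @export
blob_denoise <- function(mask, min_area, connectivity = 8) {
  if (min_area < 1) abort("min_area must be >= 1")
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  out <- mask
  out[lab > 0L & sizes[pmax(lab, 1L)] < min_area] <- 0
  out
}

#' Perpendicular distance from a point to a line
#'
#' Distance from `(x0, y0)` to the line `A x + B y + C = 0`:
#' `|A x0 + B y0 + C| / sqrt(A^2 + B^2)`.
#'
#' @param point Numeric `c(x0, y0)`.
#' @param line Numeric `c(A, B, C)` with `(A, B) != (0, 0)`.
#' @return Nonnegative distance in pixels.
#' @export
point_line_distance <- function(point, line) {
  A <- line[1L]; B <- line[2L]; C <- line[3L]
  if (A == 0 && B == 0) abort("degenerate line: A and B are both zero")
  abs(A * point[1L] + B * point[2L] + C) / sqrt(A^2 + B^2)
}

# internal validators -------------------------------------------------------

check_gray <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) || nrow(image) < 1 || ncol(image) < 1) {
    abort("expected a numeric intensity matrix")
  }
  if (anyNA(image) || min(image) < 0 || max(image) > 255) {
    abort("intensities must lie in [0, 255]")
  }
  invisible(image)
}

check_mask <- function(mask) {
  if (!is.matrix(mask) || !is.numeric(mask)) abort("expected a mask matrix")
  if (!all(mask %in% c(0, 255))) abort("mask values must be exactly 0 or 255")
  invisible(mask)
}

# internal: box mean with replicate (edge-clamp) padding, via 2-D cumsum
box_mean <- function(m, window) {
  h <- nrow(m); w <- ncol(m); r <- (window - 1L) %/% 2L
  ri <- pmin(pmax(seq.int(1L - r, h + r), 1L), h)
  ci <- pmin(pmax(seq.int(1L - r, w + r), 1L), w)
  p <- m[ri, ci, drop = FALSE]
  cs <- apply(p, 2L, cumsum)
  cs <- t(apply(cs, 1L, cumsum))                  # cs[i,j] = sum p[1..i, 1..j]
  cs <- rbind(0, cbind(0, cs))
  n <- window
  i1 <- seq_len(h); j1 <- seq_len(w)
  s <- cs[i1 + n, j1 + n, drop = FALSE] - cs[i1, j1 + n, drop = FALSE] -
       cs[i1 + n, j1, drop = FALSE] + cs[i1, j1, drop = FALSE]
  s / (n * n)
}
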