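# Seeded synthetic fixture generators: eyebrow bands with analytic
# descriptors, eye images with known ellipse/circle geometry, landmark sets
# with planted face ratios, and score-banded cohorts with planted
# associations. All randomness is local to the call (the caller's RNG state
# is untouched) and byte-identical under a fixed seed.

# internal: evaluate code under a temporary RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic eyebrow patch with known descriptors
#'
#' Draws a dark band of the given width along a circular arc whose chord is
#' `length` and sagitta is `apex_height`, so the ground-truth curvature (the
#' maximum chord-to-midline distance) equals `apex_height` exactly. Seeded
#' small noise blobs emulate stray hair; mild Gaussian noise is added to the
#' whole patch.
#'
#' @param length Chord length in columns (`<= frame width`). Default 85.
#' @param width Band width in pixels. Default 12.
#' @param apex_height Sagitta of the arc (ground-truth curvature), `>= 0`.
#'   Default 9.
#' @param angle Rotation of the band about the frame center, degrees.
#'   Default 0.
#' @param fg,bg Foreground (band) and background intensities. Defaults 40
#'   and 200.
#' @param noise_blobs Number of stray blobs. Default 3.
#' @param noise_size Blob pixel-size range. Default `c(2, 8)`.
#' @param noise_sd Gaussian intensity noise sd. Default 3.
#' @param frame Patch size `c(width, height)`. Default `c(100, 50)`.
#' @param seed Integer seed; fixed seeds give byte-identical patches.
#' @return List with `image` (intensity matrix) and `truth`, a one-row
#'   tibble of analytic `area` (`length * width`), `length`, `avg_width`
#'   and `curvature`.
#' @export
gen_eyebrow <- function(length = 85, width = 12, apex_height = 9, angle = 0,
                        fg = 40, bg = 200, noise_blobs = 3,
                        noise_size = c(2, 8), noise_sd = 3,
                        frame = c(100, 50), seed = 1) {
  w <- frame[1L]; h <- frame[2L]
  if (length < 3 || length > w) abort("eyebrow spec error: chord length outside frame")
  if (width < 1 || apex_height < 0) abort("eyebrow spec error: invalid width or apex")
  y0 <- ceiling((h + apex_height) / 2)
  if (y0 - apex_height - width / 2 < 1 || y0 + width / 2 > h - 2) {
    abort("eyebrow spec error: band geometry exceeds frame")
  }
  x0 <- floor((w - length) / 2)
  x1 <- x0 + length - 1
  xm <- (x0 + x1) / 2

  X <- matrix(rep(0:(w - 1), each = h), h, w)
  Y <- matrix(rep(0:(h - 1), times = w), h, w)
  if (angle != 0) {
    th <- -angle * pi / 180
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    Xr <- cx + cos(th) * (X - cx) - sin(th) * (Y - cy)
    Yr <- cy + sin(th) * (X - cx) + cos(th) * (Y - cy)
    X <- Xr; Y <- Yr
  }
  if (apex_height == 0) {
    member <- X >= x0 & X <= x1 & (Y - y0) >= -width / 2 & (Y - y0) < width / 2
  } else {
    chord <- x1 - x0
    r <- ((chord / 2)^2 + apex_height^2) / (2 * apex_height)
    yc <- y0 - apex_height + r
    d <- sqrt((X - xm)^2 + (Y - yc)^2)
    member <- X >= x0 & X <= x1 & Y < yc & d >= r - width / 2 & d < r + width / 2
  }
  img <- matrix(bg, h, w)
  img[member] <- fg

  with_seed(seed, {
    if (noise_blobs > 0) {
      for (b in seq_len(noise_blobs)) {
        size <- round(runif(1, noise_size[1L], noise_size[2L]))
        cxb <- runif(1, 3, w - 4); cyb <- runif(1, 3, h - 4)
        rb <- sqrt(size / pi)
        blob <- (X - cxb)^2 + (Y - cyb)^2 <= rb^2
        img[blob] <- fg
      }
    }
    if (noise_sd > 0) img <- img + matrix(rnorm(h * w, 0, noise_sd), h, w)
  })
  img[img < 0] <- 0; img[img > 255] <- 255

  list(image = img,
       truth = tibble(area = length * width, length = length,
                      avg_width = width, curvature = apex_height))
}

#' Generate a synthetic eye patch with known ellipse and iris geometry
#'
#' Renders a dark eye-ellipse outline and a dark iris-circle outline on a
#' light background with seeded Gaussian noise. Ground-truth areas are
#' `pi * m * n` and `pi * R^2`.
#'
#' @param center Ellipse center `c(x, y)`. Default `c(50, 25)`.
#' @param semi_axes `c(m, n)` semi-major and semi-minor axes. Default
#'   `c(30, 15)`.
#' @param rotation Ellipse rotation, degrees. Default 0.
#' @param iris_center Iris center; defaults to the ellipse center.
#' @param iris_radius Iris radius R. Default 12.
#' @param fg,bg Outline and background intensities. Defaults 60 and 200.
#' @param noise_sd Gaussian intensity noise sd. Default 2.
#' @param frame Patch size `c(width, height)`. Default `c(100, 50)`.
#' @param seed Integer seed.
#' @return List with `image`, `truth` (one-row tibble `eye_area`,
#'   `iris_area`, `iris_ratio`) and `params`.
#' @export
gen_eye <- function(center = c(50, 25), semi_axes = c(30, 15), rotation = 0,
                    iris_center = NULL, iris_radius = 12, fg = 60, bg = 200,
                    noise_sd = 2, frame = c(100, 50), seed = 1) {
  w <- frame[1L]; h <- frame[2L]
  m <- semi_axes[1L]; n <- semi_axes[2L]
  if (m < n) abort("eye spec error: semi-major axis smaller than semi-minor")
  if (is.null(iris_center)) iris_center <- center
  th <- rotation * pi / 180
  tt <- seq(0, 2 * pi, length.out = 1441L)[-1441L]
  ex <- center[1L] + m * cos(tt) * cos(th) - n * sin(tt) * sin(th)
  ey <- center[2L] + m * cos(tt) * sin(th) + n * sin(tt) * cos(th)
  if (min(ex) < 1 || max(ex) > w - 2 || min(ey) < 1 || max(ey) > h - 2) {
    abort("eye spec error: ellipse exceeds frame")
  }
  # iris containment: every iris boundary point strictly inside the ellipse
  it <- seq(0, 2 * pi, length.out = 721L)[-721L]
  ix <- iris_center[1L] + iris_radius * cos(it)
  iy <- iris_center[2L] + iris_radius * sin(it)
  xp <- cos(th) * (ix - center[1L]) + sin(th) * (iy - center[2L])
  yp <- -sin(th) * (ix - center[1L]) + cos(th) * (iy - center[2L])
  if (any((xp / m)^2 + (yp / n)^2 >= 1)) {
    abort("eye spec error: iris circle not contained in eye ellipse")
  }

  img <- matrix(bg, h, w)
  stamp <- function(px, py) {
    rr <- round(py) + 1L; cc <- round(px) + 1L
    keep <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    img[cbind(rr[keep], cc[keep])] <<- fg
  }
  stamp(ex, ey)
  stamp(ix, iy)
  with_seed(seed, {
    if (noise_sd > 0) img <- img + matrix(rnorm(h * w, 0, noise_sd), h, w)
  })
  img[img < 0] <- 0; img[img > 255] <- 255

  list(image = img,
       truth = tibble(eye_area = pi * m * n, iris_area = pi * iris_radius^2,
                      iris_ratio = iris_radius^2 / (m * n)),
       params = list(center = center, semi_axes = semi_axes,
                     rotation = rotation, iris_center = iris_center,
                     iris_radius = iris_radius))
}

# canvas layout shared by the landmark generator and the cohort compositor
face_layout <- function() {
  list(frame = c(240, 320), nose_x = 120, chin = c(120, 300), half_width = 85,
       jaw_y = 200,
       brow_left = c(10, 130), brow_right = c(130, 130),   # region origins
       eye_left = c(10, 185), eye_right = c(130, 185),
       region = c(100, 50),
       brow_pad = c(4, 10), eye_pad = c(10, 15))
}

#' Generate a synthetic 68-point landmark set with a planted face ratio
#'
#' Builds a canonical flat-shaded frontal face whose widest jaw chord D1 is
#' fixed and whose hairline point is placed so that `face_ratio()` returns
#' `target_ratio` exactly. The four named templates use the typical ratios
#' 0.754 (square), 0.791 (oval), 0.872 (round) and 0.736 (heart). The
#' rendered image has a dark hair cap above the hairline row so the
#' hairline detector can be exercised.
#'
#' @param template One of `"square"`, `"oval"`, `"round"`, `"heart"`.
#' @param target_ratio Planted D1/D2 in `(0.4, 1.3)`; defaults to the
#'   template's typical ratio.
#' @param jitter Gaussian landmark jitter sd in pixels. Default 0.
#' @param seed Integer seed (used for jitter only).
#' @return List with `landmarks` (a [landmark_set()] including the hairline
#'   point), `image` (the flat-shaded face) and `truth` (one-row tibble
#'   `template`, `ratio`, `D1`, `D2`, `hairline_y`).
#' @export
gen_face_landmarks <- function(template = c("square", "oval", "round", "heart"),
                               target_ratio = NULL, jitter = 0, seed = NULL) {
  template <- match.arg(template)
  defaults <- c(square = 0.754, oval = 0.791, round = 0.872, heart = 0.736)
  if (is.null(target_ratio)) target_ratio <- defaults[[template]]
  if (target_ratio <= 0.4 || target_ratio >= 1.3) {
    abort("target_ratio must lie in (0.4, 1.3)")
  }
  lay <- face_layout()
  D1 <- 2 * lay$half_width
  D2 <- D1 / target_ratio
  hair_y <- lay$chin[2L] - D2

  pts <- matrix(NA_real_, 68, 2)
  t8 <- seq(0, 1, length.out = 9)
  pts[1:9, 1] <- lay$nose_x - lay$half_width * cos(t8 * pi / 2)       # jaw 0-8
  pts[1:9, 2] <- lay$jaw_y + (lay$chin[2L] - lay$jaw_y) * sin(t8 * pi / 2)
  pts[10:17, 1] <- 2 * lay$nose_x - rev(pts[1:8, 1])                  # jaw 9-16
  pts[10:17, 2] <- rev(pts[1:8, 2])
  # brows 17-21 / 22-26: extremes chosen so the padded bbox is one region
  bx <- seq(lay$brow_left[1L] + lay$brow_pad[1L],
            lay$brow_left[1L] + lay$region[1L] - 1 - lay$brow_pad[1L],
            length.out = 5)
  by <- lay$brow_left[2L] + c(lay$region[2L] - 1 - lay$brow_pad[2L],
                              20, lay$brow_pad[2L], 20,
                              lay$region[2L] - 1 - lay$brow_pad[2L])
  pts[18:22, ] <- cbind(bx, by)
  pts[23:27, ] <- cbind(2 * lay$nose_x - 1 - rev(bx), rev(by))
  pts[28:31, ] <- cbind(rep(lay$nose_x, 4), seq(215, 245, length.out = 4))  # bridge
  pts[32:36, ] <- cbind(seq(100, 140, length.out = 5), rep(255, 5))         # nostrils
  ex0 <- lay$eye_left[1L] + lay$eye_pad[1L]
  ex1 <- lay$eye_left[1L] + lay$region[1L] - 1 - lay$eye_pad[1L]
  ey0 <- lay$eye_left[2L] + lay$eye_pad[2L]
  ey1 <- lay$eye_left[2L] + lay$region[2L] - 1 - lay$eye_pad[2L]
  eyc <- (ey0 + ey1) / 2
  exm <- ex0 + c(1, 2) * (ex1 - ex0) / 3
  left_eye <- rbind(c(ex0, eyc), c(exm[1], ey0), c(exm[2], ey0),
                    c(ex1, eyc), c(exm[2], ey1), c(exm[1], ey1))
  pts[37:42, ] <- left_eye
  pts[43:48, ] <- cbind(2 * lay$nose_x - 1 - left_eye[c(4, 3, 2, 1, 6, 5), 1],
                        left_eye[c(4, 3, 2, 1, 6, 5), 2])
  mt <- seq(0, 2 * pi, length.out = 21)[-21]
  pts[49:68, ] <- cbind(lay$nose_x + 15 * cos(mt), 275 + 8 * sin(mt))   # mouth

  if (jitter > 0) {
    pts <- pts + with_seed(seed, matrix(rnorm(136, 0, jitter), 68, 2))
  }
  lms <- landmark_set(pts, hairline = c(lay$nose_x, hair_y))

  img <- matrix(200, lay$frame[2L], lay$frame[1L])
  cap <- max(0L, min(round(hair_y), lay$frame[2L]))
  if (cap > 0) img[seq_len(cap), ] <- 40
  list(landmarks = lms, image = img,
       truth = tibble(template = template, ratio = target_ratio,
                      D1 = D1, D2 = D2, hairline_y = hair_y))
}
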