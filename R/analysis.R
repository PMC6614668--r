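# Band-wise matching analyses over a scored cohort: score banding,
# large-eye fractions, the curvature/eye-area trend, face-ratio means by
# curvature interval, and configurable feature histograms.

default_hist_bins <- function() {
  list(brow_length = seq(60, 100, 10),
       curvature = c(0, 5, 9, 13, 17, 25),
       brow_area = seq(500, 1300, 200),
       brow_avg_width = seq(7, 15, 2),
       iris_area = seq(100, 700, 100),
       iris_ratio = seq(0.3, 0.8, 0.1),
       eye_area = seq(400, 1200, 200))
}

#' Assign attractiveness-score bands
#'
#' Bins records by score into half-open intervals over `edges`, the final
#' bin closed (with the default edges: `[2,3)`, `[3,4)`, `[4,5]`). Records
#' below the first edge are collected into an `"other"` band.
#'
#' @param records Data frame with a `score` column in `[1, 5]`.
#' @param edges Increasing bin edges. Default `c(2, 3, 4, 5)`.
#' @return `records` with a `band` factor column prepended after
#'   `score`-preserving columns.
#' @export
bin_by_score <- function(records, edges = c(2, 3, 4, 5)) {
  stopifnot(is.data.frame(records), "score" %in% names(records))
  if (any(records$score < 1 | records$score > 5, na.rm = TRUE)) {
    abort("scores must lie in [1, 5]")
  }
  nb <- length(edges) - 1L
  labels <- vapply(seq_len(nb), function(i) {
    sprintf("[%g,%g%s", edges[i], edges[i + 1L], if (i == nb) "]" else ")")
  }, character(1))
  idx <- findInterval(records$score, edges, rightmost.closed = TRUE)
  band <- ifelse(idx >= 1 & idx <= nb, labels[pmax(idx, 1L)], "other")
  records$band <- factor(band, levels = c(labels, "other"))
  as_tibble(records)
}

#' Fraction of large eyes per band
#'
#' Per band, the fraction of records whose eye area strictly exceeds the
#' threshold.
#'
#' @param records Banded records (see [bin_by_score()]) with `eye_area`.
#' @param threshold Area threshold in squared pixels. Default 800.
#' @return Tibble `band`, `n`, `fraction_large_eyes`.
#' @export
fraction_large_eyes <- function(records, threshold = 800) {
  stopifnot("band" %in% names(records), "eye_area" %in% names(records))
  out <- dplyr::summarise(
    dplyr::group_by(records, .data$band),
    n = dplyr::n(),
    fraction_large_eyes = mean(.data$eye_area > threshold, na.rm = TRUE),
    .groups = "drop")
  dplyr::filter(out, .data$n > 0)
}

#' Eyebrow-curvature versus eye-area trend per band
#'
#' Spearman rank correlation and ordinary least-squares slope of eye area
#' on eyebrow curvature within each band, with the underlying scatter
#' retained for plotting. A band with constant curvature gets `NA`
#' statistics and a flag.
#'
#' @param records Banded records with `curvature` and `eye_area`.
#' @return An object of class `curvature_trend`: a tibble with one row per
#'   band (`band`, `n`, `spearman_rho`, `ols_slope`, `flag`) carrying the
#'   scatter table as attribute `"scatter"`.
#' @export
curvature_eye_trend <- function(records) {
  stopifnot(all(c("band", "curvature", "eye_area") %in% names(records)))
  cc <- dplyr::filter(records, stats::complete.cases(records[, c("curvature", "eye_area")]))
  stats_tbl <- dplyr::summarise(
    dplyr::group_by(cc, .data$band),
    n = dplyr::n(),
    spearman_rho = if (dplyr::n() >= 3 && sd(.data$curvature) > 0)
      cor(.data$curvature, .data$eye_area, method = "spearman") else NA_real_,
    ols_slope = if (dplyr::n() >= 3 && sd(.data$curvature) > 0)
      coef(lm(.data$eye_area ~ .data$curvature))[[2]] else NA_real_,
    flag = if (dplyr::n() < 3) "n<3"
      else if (sd(.data$curvature) == 0) "constant-curvature" else "ok",
    .groups = "drop")
  structure(stats_tbl,
            scatter = dplyr::select(cc, "band", "curvature", "eye_area"),
            class = c("curvature_trend", class(stats_tbl)))
}

#' Mean face ratio per eyebrow-curvature interval
#'
#' Groups records into curvature intervals and reports the per-interval
#' mean D1/D2 face ratio within each band; empty intervals are omitted.
#'
#' @param records Banded records with `curvature` and `face_ratio`.
#' @param curvature_bin_edges Interval edges in pixels. Default
#'   `c(0, 5, 9, 13, 17, 25)`.
#' @return Tibble `band`, `curvature_bin` (factor, interval label),
#'   `bin_mid`, `n`, `mean_ratio`.
#' @export
ratio_by_curvature_bins <- function(records,
                                    curvature_bin_edges = c(0, 5, 9, 13, 17, 25)) {
  stopifnot(all(c("band", "curvature", "face_ratio") %in% names(records)))
  cc <- dplyr::filter(records, !is.na(.data$curvature) & !is.na(.data$face_ratio))
  cc$curvature_bin <- cut(cc$curvature, curvature_bin_edges,
                          include.lowest = TRUE, right = FALSE, dig.lab = 6)
  mids <- (head(curvature_bin_edges, -1) + tail(curvature_bin_edges, -1)) / 2
  out <- dplyr::summarise(
    dplyr::group_by(cc, .data$band, .data$curvature_bin),
    n = dplyr::n(), mean_ratio = mean(.data$face_ratio), .groups = "drop")
  out <- dplyr::filter(out, !is.na(.data$curvature_bin))
  out$bin_mid <- mids[as.integer(out$curvature_bin)]
  dplyr::relocate(out, "band", "curvature_bin", "bin_mid", "n", "mean_ratio")
}

#' Per-band feature histograms
#'
#' Counts records per configured interval for each available feature
#' column (defaults follow the descriptive figure axes: eyebrow length,
#' curvature, area and width; iris area, iris ratio, eye area).
#'
#' @param records Banded records.
#' @param bins Named list of bin-edge vectors, by feature column; defaults
#'   from `default_hist_bins()`. Values outside the edges fall into open
#'   outer bins.
#' @return Tibble `band`, `feature`, `bin` (interval label), `count`;
#'   counts sum to the band size for every feature.
#' @export
feature_histograms <- function(records, bins = default_hist_bins()) {
  stopifnot("band" %in% names(records))
  feats <- intersect(names(bins), names(records))
  purrr::map_dfr(feats, function(f) {
    edges <- c(-Inf, bins[[f]], Inf)
    cc <- records[!is.na(records[[f]]), ]
    cc$bin <- cut(cc[[f]], edges, include.lowest = TRUE, right = FALSE,
                  dig.lab = 6)
    out <- dplyr::count(dplyr::group_by(cc, .data$band), .data$bin,
                        .drop = FALSE, name = "count")
    out <- dplyr::ungroup(out)
    out$feature <- f
    dplyr::relocate(out, "band", "feature", "bin", "count")
  })
}

#' Full banded report of a scored feature table
#'
#' Convenience wrapper running [bin_by_score()] and the four band-wise
#' analyses, the JSON-serializable report written by the pipeline.
#'
#' @param records Feature table with `score`, `eye_area`, `curvature`,
#'   `face_ratio` columns.
#' @param eye_threshold Large-eye threshold. Default 800.
#' @param curvature_bin_edges Passed to [ratio_by_curvature_bins()].
#' @param hist_bins Passed to [feature_histograms()].
#' @return A list of tibbles: `band_sizes`, `large_eyes`, `trend`,
#'   `ratio_by_curvature`, `histograms`.
#' @export
band_report <- function(records, eye_threshold = 800,
                        curvature_bin_edges = c(0, 5, 9, 13, 17, 25),
                        hist_bins = default_hist_bins()) {
  banded <- if ("band" %in% names(records)) as_tibble(records) else bin_by_score(records)
  trend <- curvature_eye_trend(banded)
  attr(trend, "scatter") <- NULL
  class(trend) <- class(tibble())
  list(
    band_sizes = dplyr::count(banded, .data$band, name = "n", .drop = FALSE),
    large_eyes = fraction_large_eyes(banded, eye_threshold),
    trend = trend,
    ratio_by_curvature = ratio_by_curvature_bins(banded, curvature_bin_edges),
    histograms = feature_histograms(banded, hist_bins))
}
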