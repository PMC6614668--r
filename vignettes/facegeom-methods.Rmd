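---
title: "Methods: geometric eyebrow, eye and face-shape models in facegeom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric eyebrow, eye and face-shape models in facegeom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facegeom)
```

This vignette documents the models the package implements, the parameters
that matter, the numerical choices behind them, what the synthetic
generator does and does not emulate, and the known limitations. Everything
quantitative stated here is computed by the test suite or the acceptance
script; nothing is asserted beyond what those runs check.

## Conventions

All rasters are numeric matrices with rows indexing `y` (top to bottom)
and columns indexing `x`; point sets, landmarks and line coefficients use
0-based pixel coordinates with the origin at the top-left pixel. Images
hold intensities in [0, 255]; masks hold exactly {0, 255}. RGB images are
reduced to luminance with the ITU-R BT.601 weights, fixed for
reproducibility. Feature patches are normalized to 100 × 50 pixels with
bilinear resampling (chosen because it is standard and deterministic; the
identity-size case bypasses resampling and is pixel-exact).

## Eyebrow model

Segmentation thresholds each pixel against its local box mean:
`T = mean(window × window neighborhood) − offset`, with replicate padding
at borders. Written literally, marking `gray ≥ T` as white would make the
*bright* skin the foreground; the foreground of interest is the dark
eyebrow, so the default polarity marks `gray < T` as white (the literal
bright-foreground form is available as an option). Blob analysis then
removes foreground components smaller than `min_blob` pixels.

Parameters, all exposed:

* `window = 15` px — the neighborhood must be wider than the eyebrow's
  vertical thickness (typically 11–13 px in the normalized frame) so the
  local mean still samples background; 15 is the smallest odd size that
  comfortably satisfies this.
* `offset = 6` intensity units. The offset must exceed the background
  noise amplitude: with an offset of 2, zero-mean noise of a few intensity
  units makes roughly a quarter of background pixels fall below the local
  mean minus offset, and at that density speckle percolates into
  connected clusters that occasionally survive any reasonable `min_blob`.
  Six units suppresses speckle for noise up to σ ≈ 3 while remaining far
  below the eyebrow/skin contrast (≈ 160 units in typical patches).
* `min_blob = 30` px — well below any real eyebrow area (≈ 1000 px²),
  well above stray-hair blobs.

The midline curve takes, for each foreground-bearing column, the midpoint
of the minimum and maximum foreground rows; a .5 tie rounds down (floor),
fixed for determinism. Consecutive column points are connected with
8-connected Bresenham segments; **length** is the raster pixel count of
that polyline, so a 45° segment contributes one pixel per column.
**Curvature** fits the line through the two endpoint curve points (two-point
form; a vertical line when the endpoints share a column) and returns the
maximum perpendicular point-to-line distance over interior points,
endpoints excluded. Degenerate inputs (fewer than 2 foreground columns,
fewer than 3 curve points, coincident endpoints) raise descriptive errors
rather than returning sentinel values.

## Eye model

Edges come from the 3 × 3 Sobel kernels (replicate padding), binarized at
`magnitude_threshold = 0.25` of the maximum magnitude; a constant patch
yields an empty mask rather than an error.

**Direct least-squares ellipse fit.** The conic
`a x² + b x y + c y² + d x + e y + f = 0` is fitted by minimizing ‖DA‖²
subject to `4ac − b² = 1`, i.e. `AᵀCA = 1` with the constraint matrix `C`
(nonzeros C[1,3] = C[3,1] = 2, C[2,2] = −1; spectrum {−2, −1, 2, 0, 0, 0}).
The stationarity condition is the generalized eigenproblem `SA = λCA` with
`S = DᵀD`. Numerical choices:

* Points are centered and isotropically scaled before building `D`
  (conditioning); coefficients are transformed back exactly, so the fit is
  translation- and scale-equivariant to ~1e−6 (tested).
* Because `C` is singular and `S` is singular for noiseless data, the
  eigenproblem is solved by the block partitioning of the design matrix
  into quadratic and linear columns, reducing it to a 3 × 3 eigenproblem;
  the eigenvector with `4ac − b² > 0` is the solution, and across random
  point sets exactly one generalized eigenvalue is positive (tested over
  200 seeded sets).
* The coefficient vector is scaled by `μ = 1/√(uᵀCu)` so the constraint
  holds exactly; this equals the textbook `√(λ/uᵀSu)` whenever `Su = λCu`
  but is also defined in the noiseless limit where `uᵀSu = 0`. The overall
  sign is fixed so `a + c > 0`, which makes the semi-axis formulas real.
* Semi-axes use the standard conic formulas with `m ≥ n` enforced by
  construction; the major-axis orientation is `θ = ½·atan2(−b, c − a)`
  (the eigenvector of the smaller eigenvalue of the quadratic-form
  matrix). Collinear input or a non-elliptic solution raises
  "ellipse fit failed".

**Circle fit.** The algebraic model `x² + y² + a x + b y + c = 0` is
linear in (a, b, c); the normal equations are solved via QR on the design
matrix (same minimizer, better conditioning), then center and radius
follow. Collinear points (design rank < 3) raise "circle fit failed". The
fit agrees with a brute-force BFGS minimization of the algebraic objective
to 1e−4 on seeded noisy instances (tested).

**Contour separation.** Which edge pixels belong to the eye outline and
which to the iris is not determined by the operators themselves, so the
package uses an explicit, replaceable policy:

1. 3 × 3 morphological closing of the edge mask bridges one-pixel gaps.
2. The largest 8-connected component is selected.
3. A provisional ellipse is fitted to the component's *outer envelope*
   (per-column and per-row extremal pixels). The envelope matters: when
   the iris circle approaches the eye ellipse (radius close to the
   semi-minor axis), the two edge bands merge into a single component and
   a provisional fit on all points would land between the two contours,
   beyond repair by any subsequent outlier rule. The outer envelope is
   dominated by the eye outline regardless of merging.
4. Points are trimmed iteratively (3 rounds): each round keeps points
   whose signed radial distance from the current ellipse is within
   `band_px = 2` px of the median distance, then refits. Two pixels is the
   halfwidth of the edge band a thresholded 3 × 3 Sobel paints around a
   contour — a property of the operator, not of any particular image — so
   the trim converges onto the full two-sided band and the final fit is
   centered on the true contour rather than biased outward.

Iris candidates are edge points strictly inside the fitted eye ellipse
with both semi-axes scaled by `iris_factor = 0.9`, followed by the same
median-centered ±2 px radial trim against a provisional circle fit (2
rounds). An iris ratio above 1 is flagged (`fit_flags = "iris_ratio>1"`)
and warned about, not silently clipped.

## Face shape

D1 is defined as the longest *Euclidean* chord among opposing jaw-landmark
pairs (i, 16 − i), i = 0..5 (configurable to a fixed pair such as (0, 16)).
Selecting by Euclidean span rather than horizontal span keeps the ratio
exactly invariant under image-plane rotation, which the package guarantees
to 1e−9 (tested); for near-frontal faces the two selections coincide. D2
runs from the hairline point to the chin landmark (index 8); whether the
face height should end at the chin landmark or the lowest contour pixel is
ambiguous, and the chin landmark is used and recorded.

The hairline detector is this package's own construction (no standard
exists): scan upward from the brow line along the vertical through the
nose-bridge landmark, average the vertical central-difference gradient
over a 5-column band, and return the first row (moving up) where it
exceeds `grad_threshold = 30` intensity units/row for `k = 2` consecutive
rows. If no transition is found, an offset fallback point (brow line minus
0.6 × the eyes-to-chin distance) is returned and flagged, or an error is
raised when the fallback is disabled. The detector sits behind a small
interface so alternatives can be swapped.

## Synthetic generator

The generator produces the study conditions the analyses are validated
under:

* **Eyebrow bands** are drawn along a circular arc parameterized by chord
  (length) and sagitta (apex height), so the curvature statistic has the
  closed-form ground truth *curvature = sagitta*; width is the band's
  perpendicular thickness and area ≈ length × width. Stray blobs (2–8 px)
  and Gaussian intensity noise (σ = 3) emulate hair interference and
  sensor noise.
* **Eye images** render one-pixel-thick dark outlines of a planted
  ellipse and iris circle (rasterization keeps every outline pixel within
  0.75 px of its analytic curve, tested); ground-truth areas are exact
  formulas.
* **Landmark sets** scale a canonical 68-point template so the planted
  face ratio is returned exactly; the rendered flat-shaded face has a dark
  hair cap at the planted hairline row.
* **Cohorts** (default 92/146/62 records for bands [2,3), [3,4), [4,5])
  draw per-band `(curvature, eye area)` from a Gaussian copula with
  correlations (−0.2, −0.4, −0.6), transformed to the empirical ranges of
  the emulated data: eyebrow lengths 80–90 px, widths 11–13 px, curvature
  N(9, 4) clipped to [0.5, 22] px (about two-thirds of mass in 5–13 px);
  eye areas N(μ_band, 80) clipped to [600, 1000] px² with per-band means
  (745, 792, 812) chosen so the planted fraction of areas above 800 px²
  is 0.246/0.460/0.560; iris ratios N(0.55, 0.03) clipped to
  [0.45, 0.65]; face ratio 0.80 + slope_band × (curvature − 9) + N(0,
  0.03) clipped to [0.70, 0.92] with slopes (0, 0.004, 0.006). All
  clipping bounds sit strictly outside the thresholds the analyses use,
  so clipping does not move the planted fractions.

One deliberate compromise: a planted iris ratio of 0.5–0.6 cannot coexist
with an iris circle strictly inside a 2:1 eye ellipse (the circle radius
would exceed the semi-minor axis — in real faces the fitted iris circle
protrudes past the eyelid-bounded eye outline, which the outline renderer
does not model). The cohort therefore derives each record's ellipse aspect
from its planted area and ratio so containment holds, yielding rounder
synthetic eyes (aspect ≈ 1.05–2.2) than typical real ones.

What the generator does **not** emulate: photographic texture, eyelashes
and eyelid folds, illumination gradients, makeup, occlusion by hair, pose
variation, and landmark-detector error (synthetic landmarks are placed by
construction, not predicted). Passing round-trip tests therefore
demonstrates the correctness and internal consistency of the geometry and
statistics, not segmentation robustness on photographs.

## Analysis layer

Score bins are left-closed with the final bin closed ([2,3), [3,4),
[4,5]); scores below the first edge go to an explicit `"other"` band.
Eyebrow and eye features are averaged across sides for the per-image
analysis table (per-side values stay in `features.csv`); which side the
emulated study used is unknown, so the mean is the documented default, not
a claim. Default curvature intervals for the ratio-by-curvature table are
[0, 5, 9, 13, 17, 25] px, aligned with the curvature marginal above.
Spearman's rank correlation is reported as the trend statistic (the
association of interest is monotone, not necessarily linear), with the OLS
slope alongside; both are this package's formalization of a qualitative
claim and are labeled as such in reports.

The CLI accepts a YAML config for all thresholds and window sizes.

## Problem sizes and determinism

The default test run fits ellipses/circles on 50–100-point contours,
round-trips 50 seeded eyebrows, and materializes the 62-record top band of
20 seeded cohorts (about 1,200 image extractions) plus one full 300-record
cohort; the whole suite completes in about 75 s on one CPU. Every source
of randomness is seeded; generators restore the caller's RNG state, and
identical seeds give byte-identical artifacts (tested).

## Known limitations

* Eye-area extraction from the flat-shaded synthetic renders carries a
  systematic negative bias of roughly 10–15% for low-aspect eyes whose
  iris edge band touches the eye outline everywhere; ranks are preserved
  almost perfectly (Spearman ≈ 0.99 against truth), so banded association
  analyses are unaffected, but absolute thresholds (e.g. the 800 px²
  large-eye cut) should be applied to planted or calibrated areas, not raw
  extracted ones.
* The adaptive threshold hollows out dark regions thicker than the
  neighborhood window; eyebrows in the normalized frame are safely
  thinner, but the default `window = 15` is not appropriate for
  arbitrarily scaled inputs.
* The hairline detector assumes hair darker than skin along the
  nose-bridge vertical; fringes or very light hair trigger the flagged
  fallback.
* No head-pose correction: all geometry assumes frontal neutral images.
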