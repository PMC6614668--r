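Package: facegeom
Title: Geometric Models of Eyebrows, Eyes and Face Shape for Facial Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Feature extraction and cohort analysis for frontal-face morphometrics.
    Segments eyebrows in normalized patches by adaptive mean thresholding and blob
    denoising and computes four shape descriptors (area, length, average width and
    curvature, the maximum chord-to-midline distance); fits eye contours by the
    direct least-squares ellipse method (constrained generalized eigenproblem under
    4ac - b^2 = 1) and iris contours by algebraic least-squares circle fitting;
    computes the facial transverse/longitudinal ratio D1/D2 from 68-point landmarks
    plus a hairline point. Includes a fully seeded synthetic generator for eyebrow
    bands, eye images, landmark sets and score-banded cohorts with planted
    associations, and band-wise matching analyses (large-eye fractions, eyebrow
    curvature versus eye area, face ratio versus curvature).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
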