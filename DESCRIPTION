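Package: fourpoint
Title: Error Analysis of Four-Point Plane Orientation for 3D Cephalometric Landmarks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds an anatomical 3D reference frame from four cranial-base
    landmarks (MLWS origin; axes from nasion, sella and basion), rigidly
    reorients repeated landmark digitizations into it, and quantifies how
    digitization error propagates through the superimposition: locating
    error, reorientation error, distance from the reoriented transverse
    axis, reference-point angle sums, intraclass correlation, and a stepwise
    multiple-regression error model with variance inflation diagnostics.
    Includes a seeded synthetic-cohort generator whose placement noise and
    skull geometry are calibrated to published per-landmark error
    magnitudes, so the full pipeline runs and is tested without any image
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
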