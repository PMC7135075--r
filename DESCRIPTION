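Package: hipcongruity
Title: Three-Dimensional Hip Joint Congruity Indices from Bone Surface Models
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures three-dimensional congruity of the hip joint from
    CT-derived bone surface models. Extracts a latitude-band region of
    interest on the femoral head using a femoral-neck reference frame,
    locates the femoral head center and the acetabular (lunate surface)
    curvature center by iterative grid search minimizing the standard
    deviation of point-to-center distances, and derives the 3D curvature
    mismatch ratio (acetabular over femoral radius of curvature) and the
    3D center discrepancy distance and direction. Includes a parametric
    synthetic-anatomy generator with known ground truth for validation,
    plus a command-line interface for single-hip fits, cohort summaries
    and simulation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
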