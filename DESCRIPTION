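Package: contourdose
Title: Geometric and Dosimetric Agreement Analysis for Radiotherapy
    Auto-Contour Quality Assurance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how geometric agreement between automatically
    generated and clinically edited organ-at-risk contours relates to
    dosimetric differences in head-and-neck radiotherapy plans. Computes
    volumetric Dice, surface Dice at a configurable tolerance, and
    Hausdorff distance from paired binary masks; extracts D0.01cc and
    mean-dose statistics by transposing one planned dose grid over both
    contour sets; measures each organ's Euclidean distance to the closest
    planning target volume; and applies a configurable absolute or
    prescription-relative dose-difference flagging rule with
    proximity-stratified and binned cohort summaries. Includes a seeded
    synthetic phantom-cohort generator so the full pipeline is testable
    without patient data. Volumes are read and written as NIfTI; cohorts
    are described by a JSON manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
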