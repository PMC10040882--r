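Package: cellconcord
Title: Cell-Level Concordance and Detection Evaluation for Pathology Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating cell-level annotations and detections on
    immunohistochemistry regions of interest. Establishes distance-gated
    one-to-one correspondences between annotation sets with a minimum-cost
    bipartite assignment, quantifies inter-rater agreement with Cohen's kappa
    and three missed-cell variants (Regular Category, Listwise Deletion,
    Gwet), builds multi-rater consensus annotations with majority voting and a
    tie ("diverse") class, and scores detectors with eleven-point average
    precision, non-maximum suppression and patch stitching. A synthetic
    generator of cell layouts, simulated raters and simulated detectors
    provides ground truth for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
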