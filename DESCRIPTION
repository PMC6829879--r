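Package: houghcell
Title: Quantifying Cell Elongation in Brightfield Microscopy with the
    Hough Transform
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures dynamic cellular morphology, in particular the
    elongation of adherent epithelial cells undergoing an
    epithelial-mesenchymal transition, from single-frame brightfield
    microscopy images. The pipeline converts frames to grayscale, removes
    salt-and-pepper noise with a median filter, stretches contrast with a
    cube intensity transform, extracts cell boundaries with a Canny edge
    detector, detects straight boundary segments with a Hough transform
    subject to a minimum line length, removes duplicate near-parallel
    detections, merges fragmented detections into piecewise lines (one per
    cell), and reports line counts, lengths and length-bin percentages as
    tidy tables. A seeded synthetic-scene generator with ground truth makes
    every stage testable without real microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
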