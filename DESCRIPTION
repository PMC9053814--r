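Package: blebquant
Title: Segmentation and Morphometric Analysis of Blebbing Cells in Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for quantifying plasma-membrane blebbing in
    time-lapse fluorescence microscopy of mechanically confined cells. Reads
    multi-dimensional TIFF stacks, segments the cell with selectable global
    auto-thresholding methods, splits the whole-cell mask into cell body,
    all blebs and the largest bleb per frame, computes a battery of shape
    descriptors (area, perimeter, circularity, roundness, aspect ratio,
    solidity) and percent-of-cell-area measures, tracks blebs across frames
    by mask overlap to obtain lifetimes, derives trajectories and
    instantaneous speeds, and classifies cells into leader-mobile,
    leader-non-mobile and no-leader phenotypes. Includes a synthetic-movie
    generator with ground-truth masks, tracks and phenotype labels so the
    whole pipeline is testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
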