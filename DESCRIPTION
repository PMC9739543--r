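Package: blebkit
Title: Detection and Counting of Axonal Swellings in 3D Fluorescence Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for automated detection and counting of axonal swellings
    ("blebs") in neurofilament-immunolabelled optic-nerve z-stacks. A small
    encoder-decoder convolutional network segments each optical section
    tile-by-tile; three 3D post-processing filters (slice-thickness,
    travelling-centroid elimination, morphological opening plus size
    threshold) convert per-slice segmentations into a catalog of 3D bleb
    objects; object-level agreement metrics (PPV, sensitivity, F1, Jaccard)
    compare raters or segmentations. A synthetic-scene generator plants
    axons, blebs, shifting bright segments and speckle artifacts with exact
    ground truth so every stage is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
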