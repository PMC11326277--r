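Package: stitchspot
Title: Stitch Multiple Visium Capture Areas into One Analysis-Ready Sample
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates gene-expression and imaging data from multiple 10x
    Genomics Visium capture areas (partially overlapping or adjacent) into a
    single stitched sample. Rescales per-capture-area high-resolution images
    to a uniform physical scale for external stitching with Fiji, applies the
    resulting rigid affine transforms to spot pixel coordinates, resizes the
    stitched composite image with matching scale factors, constructs an
    artificial hexagonal Visium-like array spanning the whole stitched tissue
    and snaps every spot to it so spatially-aware clustering methods work
    unchanged, flags spots in regions of overlap by mean-UMI precedence
    without discarding any data, and assembles counts, coordinates, image and
    metadata into a tidy stitched-group object with exporters to
    SpaceRanger-style outputs. A simulation module generates complete
    synthetic multi-capture-area experiments with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    xml2,
    Matrix,
    methods,
    png,
    tiff,
    EBImage,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
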