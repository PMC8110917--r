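Package: vesseltrace
Title: Microvessel Length Density from Detection Boxes via Polyline
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies microvessel length density in 2D microscopy images
    of angiogenesis assays. Converts manual vessel tracings (polylines) into
    overlapping rectangular training regions for object detectors, and
    reconstructs vessel polylines from detection boxes by neighbor-graph
    linking, image-support filtering of false connections, and minimum
    spanning tree cycle removal. Provides image preprocessing (maximum
    z-projection, histogram equalization), a classical pixel-based
    skeletonization length measurement for comparison, percent-error and
    percent-accuracy metrics with per-sample and per-group averaging,
    grouped k-fold cross-validation partitioning with leakage checks, and a
    synthetic vessel-scene generator so the whole pipeline is testable
    without trained detector weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
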