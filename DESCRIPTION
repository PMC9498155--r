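Package: tileseg
Title: Patch-Based Whole-Slide Tumor Segmentation by Sliding-Window CNN
    Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segments whole-slide histopathology images into tumor and
    normal tissue from area-based expert annotations. Provides annotation
    ingest (GeoJSON polygons) and rasterization, white-background masking,
    multi-resolution downsampling, disjoint 128x128 tile extraction with
    class balancing and by-slide splits, a compact four-layer convolutional
    patch classifier trained with SGD and early stopping, sliding-window
    per-pixel confidence aggregation with grayscale/jet rendering,
    kernel-level and pixel-level evaluation metrics, F1-driven threshold
    sweeps and step-size trade-off tables, plus a seeded synthetic-slide
    generator with two texturally distinct tissue classes so the whole
    pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'annotation_io.R'
    'cnn.R'
    'classifier.R'
    'evaluation.R'
    'segmentation.R'
    'optimization.R'
    'patching.R'
    'synthetic.R'
    'pipeline.R'
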