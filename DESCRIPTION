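Package: slideforge
Title: Tiling, Tissue Detection, Annotation Handling and Inference
    Bookkeeping for Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pre- and post-processing toolbox for gigapixel whole-slide
    images (WSIs) used in computational pathology. Opens pyramidal slides,
    defines tile grids with configurable size and overlap, detects tissue
    versus background and artefacts with both classical thresholding
    (Otsu, triangle, fixed intensity cuts) and a pluggable three-class
    tile classifier, parses QuPath-style GeoJSON and ASAP XML polygon
    annotations with doughnut-hole subtraction, extracts class-labelled
    tiles and binary or stacked segmentation masks to an image-folder
    layout, runs tile-level classifier and segmenter inference, stitches
    overlapping per-tile segmentation predictions into slide-level
    probability arrays, and evaluates predictions with threshold-sweep
    metrics and a slide-level AUROC helper. Ships a synthetic pyramidal
    slide generator so the full pipeline is testable without external
    slide downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    stats,
    utils,
    tools,
    tiff,
    png,
    jsonlite,
    xml2,
    polyclip
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
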