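Package: octdetect
Title: Transformer Lesion Detection for Speckled Tomographic B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Single-class lesion detection in noisy tomographic B-scans
    (optical coherence tomography and related modalities) with an
    attention-gated patch encoder feeding a vision-transformer trunk that
    regresses a fixed-size array of axis-aligned bounding boxes. Training
    minimises a composite loss combining coordinate mean-squared error, a
    structural-similarity difference on rasterised box masks, and an
    intersection-over-union term. Includes a synthetic speckle-scan
    generator with exact ground-truth boxes, box-aware geometric
    augmentation, dataset splitting and annotation I/O (CSV and COCO-style
    JSON), and the single-class IOU-thresholded evaluation protocol
    (accuracy, precision, sensitivity, F1, mean IOU). The network, its
    analytic backpropagation and the Adam/AdamW optimisers are implemented
    in base R matrix algebra, so the whole pipeline runs end-to-end with no
    external data or deep-learning runtime.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
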