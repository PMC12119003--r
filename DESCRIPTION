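Package: bgmyolo
Title: Lightweight Convolutional Blocks and Desk-Scale Training for Plant
    Lesion Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses a YOLOv8n-style anchor-free detector for
    plant-disease lesions, assembled from three lightweight blocks: GSConv
    based bottlenecks (GSC2f), a median-enhanced channel and spatial
    attention block (MECS), and a softmax-gated multi-scale feature fusion
    module (BFM). Ships its own tensor engine with reverse-mode automatic
    differentiation and C++ convolution kernels, an analytic parameter and
    FLOP profiler with per-layer breakdowns, a synthetic plant-lesion scene
    generator with YOLO-format dataset input/output, detection metrics
    (precision, recall, AP, mAP over IoU thresholds, confusion matrices),
    and a desk-scale training loop with task-aligned assignment and
    distribution-focal box regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
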