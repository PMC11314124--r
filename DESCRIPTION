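Package: lsdyolo
Title: Lemon Surface Disease Detection with a Configurable YOLOv8-Style Model Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A CPU reference implementation of LSD-YOLO, an anchor-free
    single-stage detector family for locating healthy and diseased lemons in
    orchard imagery. Builds the nano-scale YOLOv8-style baseline and its three
    modifications (switchable atrous convolution with C2f-SAC blocks, a
    channel/spatial attention module, and a stride-4 small-object detection
    head) as declarative model variants with exact trainable-parameter
    accounting. Includes YOLO-format dataset input/output, target-centred
    1024x1024 tiling with annotation regeneration, stratified 5-fold
    cross-validation planning, detection metrics (precision, recall, AP,
    mAP@50, mAP@50-95, fold mean and population standard deviation), a
    synthetic lemon-scene generator for fully self-contained testing, and a
    seeded AdamW training loop with task-aligned assignment, CIoU and
    distribution-focal losses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
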