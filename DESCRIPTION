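Package: wildetect
Title: One-Stage Wildlife Detection for Camera-Trap Images with Windowed
    Self-Attention and Class-Suppression Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting forest wildlife in camera-trap images with a
    compact one-stage detector. The network is a YOLOv5s-scale convolutional
    backbone and path-aggregation neck in which selected cross-stage-partial
    blocks are replaced by shifted-window multi-head self-attention (Swin
    Transformer) blocks, and every feature concatenation in the neck is
    re-weighted by squeeze-and-excitation channel attention. Training uses a
    distance-IoU box regression loss and an adaptive class-suppression
    classification loss that protects rare (tail) classes in long-tailed
    data. The package also provides box-aware dataset augmentation (rotation,
    Gaussian corruption, object-level image fusion, four-image mosaic),
    YOLO-txt and Pascal-VOC annotation input/output, PR-curve based
    evaluation (precision, recall, per-class AP, mAP at IoU 0.5, a
    background-aware confusion matrix), and a deterministic synthetic
    camera-trap scene generator so the whole stack is testable end-to-end
    without external data. A small reverse-mode automatic-differentiation
    engine with compiled convolution kernels makes CPU training of reduced
    models practical.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    png,
    yaml,
    xml2,
    jsonlite,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
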