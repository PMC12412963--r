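Package: yolocf
Title: Anchor-Based One-Stage Fruit Detection with the YOLOcF Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates the YOLOcF anchor-based one-stage
    object detector for fruit scenes, together with its ablation variants.
    Provides the network building blocks (CBS, C3, C2f and the MPC, C4, C2fR
    and SPPR modules), a scaled backbone / PAFPN neck / coupled-head assembly,
    the composite CIoU + binary cross-entropy detection loss with anchor-based
    target assignment, grid decoding and non-maximum suppression, detection
    metrics (precision, recall, mAP) and object-count regression metrics
    (MAE, RMSE, R-squared), analytic parameter and FLOPs accounting, a
    procedural generator of annotated synthetic fruit scenes in YOLO label
    format, and a small CPU training loop with mosaic and HSV augmentation.
    All tensor arithmetic runs on a lightweight reverse-mode automatic
    differentiation engine with compiled convolution and pooling kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
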