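Package: fbstrnet
Title: Lightweight Detection of Fetal Brain Structures in Early-Pregnancy Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-stage detection of twelve fetal-brain anatomical structures in
    first-trimester ultrasound standard planes. Implements a YOLOv5-s style detector
    with Ghost-module backbone substitutions and a decoupled prediction head, the
    SIoU and CIoU bounding-box regression losses, class-wise non-maximum suppression,
    a clinically informed plane-aware post-filter that keeps at most one detection
    per expected structure (two for the paired choroid plexus), and mean-average-
    precision evaluation. A synthetic ultrasound phantom generator renders speckled
    fan-beam images with plane-consistent ground truth so the full train/detect/eval
    pipeline can be exercised without clinical data. The convolutional engine
    (forward, backpropagation, SGD) is self-contained via Rcpp/RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
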