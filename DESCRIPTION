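Package: histoception
Title: Semi-Supervised Histopathology Image Classification with a
    Truncated Residual-Inception Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-class (benign vs malignant) breast-cancer
    histopathology image classification on BreakHis-style,
    magnification-stratified image collections. Implements a lightweight
    model family that truncates a 50-layer residual backbone after its
    third convolutional stage and fuses it with a naive-inception head
    (parallel 1x1, 3x3 and 5x5 convolutions plus a 3x3 maxpool,
    channel-concatenated), exact closed-form parameter auditing of every
    weight, bias and batch-normalization statistic, block-wise
    freeze/fine-tune configurations, an exponentially decaying
    learning-rate schedule with a floor, and a confidence-thresholded
    pseudo-label self-training loop that grows a small labeled pool from
    an unlabeled one. A synthetic nuclei-blob image generator emulates
    the two-class, four-magnification directory layout so the whole
    pipeline is testable at desk scale without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
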