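Package: attrunet
Title: Attention-Gated Recurrent Residual U-Net for Lesion Segmentation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fully automated binary lesion segmentation of 2-D grayscale
    medical images with an attention-gated recurrent residual U-Net. The
    package implements the architecture from first principles -- soft spatial
    attention gates on the skip connections, recurrent convolutional layers
    with in-loop batch normalization, residual recurrent convolution blocks --
    together with Z-score intensity normalization, binary cross-entropy
    training with Adam, a five-metric evaluation suite (Dice, Jaccard,
    precision, specificity, sensitivity) with precision-recall curves,
    patient-wise k-fold cross-validation, an ablation-variant factory, and a
    synthetic MRI-phantom cohort generator for end-to-end testing without
    protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
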