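Package: watunet
Title: Wavelet-Attention UNet for Breast Ultrasound Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of hypoechoic breast lesions in B-mode ultrasound
    with a UNet-style encoder-decoder whose skip connections are replaced by
    wavelet gates (single-level Db2 discrete wavelet transform with sub-band
    routing) and additive attention gates. Includes a seeded synthetic
    speckle-phantom generator, CLAHE enhancement and paired geometric
    augmentation, a combined binary cross-entropy plus Dice training loss,
    a confusion-matrix metric suite with 0.4 binarization, and pairwise
    pixelwise McNemar tests with Benjamini-Hochberg false discovery rate
    control for model comparison. All network forward and backward passes
    are implemented in R and C++; no external deep-learning framework is
    required.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
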