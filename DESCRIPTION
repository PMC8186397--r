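Package: osteoquant
Title: Automated Quantification of TRAP-Stained Osteoclast Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection, classification and quantification of osteoclasts in
    TRAP-stained culture-well micrographs. Provides a patch-trained
    single-shot detector (anchor boxes, multibox loss, non-maximum
    suppression, Adam-trained convolutional backbone), training-set
    amplification by random sub-patch sampling with photometric and
    geometric augmentation, tiled whole-well inference, per-class cell
    counts and union covered-area endpoints, per-region Pearson agreement
    statistics with residual-normality checks, LabelMe-compatible polygon
    annotation I/O, and a seeded synthetic TRAP-culture generator with
    exact ground truth for training and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
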