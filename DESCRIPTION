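Package: randnet
Title: Ensemble Classification of Stem-Cell Images with an Autoencoded
    Feature Extractor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements RandNet, a bagging ensemble of convolutional
    subnetworks for classifying cropped phase-contrast images of human
    embryonic stem cells into six morphological classes (cell cluster,
    debris, unattached cell, attached cell, dynamically blebbing cell,
    apoptotically blebbing cell).  A convolutional autoencoder is
    pretrained on unlabeled crops with a pixel-wise binary cross-entropy
    loss; its encoder is cloned into n subnetworks that are fine-tuned on
    stratified bootstrap resamples of the labeled pool, and a small
    stacking network fuses the subnetwork outputs into the final decision.
    Also provides a seeded synthetic generator of the six image classes, a
    stratified split / k-fold / bootstrap data pipeline, and
    confusion-matrix evaluation (overall accuracy and per-class recall).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    EBImage,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
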