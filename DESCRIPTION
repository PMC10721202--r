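Package: sparsebeauty
Title: Activation Sparsity of Deep Visual Codes as a Predictor of Beauty Ratings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies processing-based aesthetics: computes layer-wise
    activation sparsity (Gini index, Treves-Rolls sparseness) of images
    under a convolutional encoder, reduces per-layer activations with PCA,
    and fits a battery of repeated cross-validated linear and ridge
    regression models predicting mean-opinion beauty scores from sparsity
    and principal-component features. Includes a seeded fixture encoder
    and a synthetic-data generator with known ground truth so every stage
    is testable without external image datasets or pretrained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
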