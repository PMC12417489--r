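Package: eegalign
Title: Contrastive Alignment of Clinical EEG and Report Text
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A contrastive language-EEG pretraining toolkit for clinical
    neurophysiology. Pairs windows of multi-channel EEG with the free-text
    medical report of the same recording and trains a dual-encoder model
    (a four-block convolutional EEG encoder and a pluggable text encoder,
    each followed by an MLP projection head) under an InfoNCE-style loss in
    a shared embedding space. Supports zero-shot classification from text
    prompt prototypes, frozen-encoder probing, few-shot evaluation
    protocols, frequency-domain gradient attribution, clinical report
    section parsing and label derivation, and a synthetic generator of
    paired EEG recordings and templated reports for end-to-end testing
    without access-gated corpora. All neural-network primitives (1-D
    convolution, batch normalization, max pooling, dropout, Adam) are
    implemented on base BLAS matrix operations, so the package runs on a
    plain CPU R installation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
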