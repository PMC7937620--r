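Package: netimage
Title: Image-Like Network Representations for Disease-Gene Classification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts each vertex of a weighted biological network into a
    small image-like matrix: the adjacency of a node-induced sub-network
    built from a similarity-based receptive field on the hierarchical
    clustering leaf order, plus a diagonal matrix of neighbouring genes'
    disease-class values. Includes balanced binary classification of
    target-class genes with a small convolutional neural network and five
    classical learners, multi-network fusion by elementwise averaging,
    a no-environment baseline, evaluation utilities (ROC, AUC, confusion
    matrices, best threshold), and a scale-free planted-partition
    synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
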