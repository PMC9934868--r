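Package: morphodesc
Title: Unsupervised Morphology Descriptors for Cells in Segmented Volume Electron Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns per-cell morphology descriptors from a segmented 3D
    electron-microscopy-style volume without manual labels. Six small neural
    encoders (point-cloud shape, coarse texture and fine texture, for cell and
    nucleus) are trained with a contrastive NT-Xent objective plus an
    autoencoding reconstruction loss, and their 80-dimensional embeddings are
    concatenated into a 480-dimensional per-cell descriptor. The package also
    provides the surrounding pipeline: a synthetic phantom-volume generator
    with bilateral mirror symmetry, mesh extraction with deformation
    augmentations, region-adjacency-graph context features, morphotype
    classification, a bilateral symmetric-partner rank metric, k-NN-graph
    Leiden clustering and gene and feature specificity statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    glmnet,
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    readr,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
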