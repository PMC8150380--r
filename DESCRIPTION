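Package: crossess
Title: Cross-Species Prediction of Essential Genes from Harmonized Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds harmonized per-gene feature tables for two species, selects
    consensus predictive features (elastic net intersected with ensemble sparse
    partial least squares), trains and evaluates essentiality classifiers within
    species (subsample grids and bootstrap resampling on imbalanced labels),
    transfers predictions across species, and validates ranked predictions
    against an independent lethal-phenotype database via cumulative hit-ratio
    curves and chromosome-level probability tracks. Includes a synthetic
    twin-species data generator with planted cross-species signal so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    glmnet,
    xgboost,
    randomForest,
    e1071,
    nnet,
    igraph,
    Matrix,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
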