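Package: ccann
Title: Seven-State Cell Cycle Classification for Single-Cell Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies single cells into seven cell-cycle states (Neural G0,
    G1, Late G1, S, S/G2, G2/M, M/Early G1) from scRNA-seq expression using a
    fully connected artificial neural network with softmax likelihoods and a
    tunable likelihood threshold that rejects uncertain cells as "Unknown".
    Includes matrix readers and normalization (analytic Pearson residuals or
    log-CPM), gene-identifier and cross-species feature alignment with
    zero-filling of missing classifier genes, marker-gene discovery,
    hypergeometric gene-set overlap tests, bulk-signature Spearman mapping,
    permutation feature importance, cell-cycle signal regression with an
    empirical PC1-variance test, an evaluation harness (per-state F1, adjusted
    mutual information with Unknown exclusion, threshold sweeps with a
    random-removal baseline, missing-gene sensitivity, AMI similarity
    calibration, hidden-layer grid search), a labeled synthetic-data
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
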