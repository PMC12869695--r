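Package: combisyn
Title: Drug Combination Synergy Scoring and Multimodal Synergy Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for drug-combination synergy analysis: synergy
    scoring of dose-response checkerboards under the Bliss, highest-single-agent
    (HSA), Loewe and ZIP null models; chemical-fingerprint drug harmonization;
    multimodal feature engineering (Morgan fingerprints, drug-target vectors
    propagated over a protein-protein interaction network by random walk with
    restart, autoencoder expression embeddings, binary mutation profiles); an
    attention-fusion neural predictor of combination synergy trained with binary
    cross-entropy; leakage-free cross-validation splits (leave-combo-out,
    leave-drug-out, leave-sample-out); and downstream patient stratification
    (hierarchical clustering of predicted-synergy matrices, log-rank survival
    comparison, a linear-predictor-score classifier, and a largest-connected-
    component permutation test on the interactome). A pathway-structured
    synthetic-data generator with a planted, recoverable synergy rule makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
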