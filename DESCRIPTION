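Package: devrank
Title: Rank-Based Aggregation and Sparse Prediction for Antibody Developability Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Condenses a panel of antibody developability-assay outputs into a
    single Averaged Developability Output Score (ADOS) and a LASSO-selected
    Holistic Developability Parameter (HDP) that predicts a ranked
    manufacturability attribute such as the monomer-loss rate under long-term
    storage. Includes weighted linear degradation-rate estimation from
    stability time courses, Spearman correlation and group-average hierarchical
    clustering of assay variables with leave-one-sample-out stability
    statistics, percentile-based distance-from-ideal scoring, rank-uncertainty
    enumeration, and a synthetic-panel generator for validating every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
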