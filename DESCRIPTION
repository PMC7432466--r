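Package: cb2screen
Title: Ligand-Based QSAR Screening for CB2-Selective Cannabinoids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for curating cannabinoid-receptor bioactivity tables into
    per-target pKi datasets, training gradient-boosted QSAR regression models
    with a k-nearest-neighbour applicability domain defined in the ensemble's
    leaf-value embedding, cross-validated Q2 model validation with a threshold
    sweep, CB2-versus-CB1 selectivity screening with Tanimoto novelty scoring,
    and enrichment statistics (enrichment factors, ROC AUC) for docking-score
    rankings.  A synthetic-data generator produces activity tables, candidate
    libraries and docking-score lists with known ground truth so the whole
    pipeline can be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    ChemmineOB,
    xgboost,
    data.table,
    igraph,
    jsonlite,
    rlang,
    stats,
    utils,
    tibble,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
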