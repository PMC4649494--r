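Package: katzlda
Title: KATZ Walk-Counting Prediction of lncRNA-Disease Associations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate lncRNA-disease associations with the KATZ
    measure on a heterogeneous network built from known associations,
    ontology-based disease semantic similarity, lincRNA expression
    similarity, imported lncRNA functional similarity, and Gaussian
    interaction-profile kernels. Includes the rank-based evaluation
    protocol (global/local leave-one-out and repeated 5-fold
    cross-validation with ROC/AUC) and seeded synthetic-data generators
    for every pipeline input.
License: MIT
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
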