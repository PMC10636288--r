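Package: dnasearch
Title: Ant Colony Architecture Search for Cancer Subtype Classifiers
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated configuration of a regularized feed-forward
    classifier for cancer-subtype identification from gene-expression
    matrices. Candidate architectures (depth, layer widths, activations,
    dropout, batch normalization, L1/L2 penalties, optimizer, learning
    rate, epochs) are searched by an ant colony system over a layered
    hyperparameter graph, guided by a gradient-boosted-tree surrogate
    whose feature importances supply the heuristic information. Includes
    a one-vs-rest differential-expression gene filter (Welch t-test and
    Wilcoxon rank-sum with Benjamini-Hochberg control and a fold-change
    gate), a synthetic multiclass expression-data generator with planted
    class-informative genes, macro per-class evaluation metrics,
    leakage-safe stratified cross-validation, and a command-line
    interface covering the full simulate/select/search/train/predict/
    evaluate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    matrixStats,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
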