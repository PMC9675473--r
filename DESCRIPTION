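Package: nephromac
Title: Single-Cell and Spatial Transcriptomic Analysis of Kidney
    Macrophages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for the bespoke computational stages of a
    combined single-cell and Visium spatial study of kidney mononuclear
    phagocytes in lupus nephritis: quality control and median-target
    normalization of 10x count matrices, cluster-level doublet flagging
    from per-cell doublet scores (robust z of cluster medians, one-tailed
    test, Benjamini-Hochberg), AUCell-style gene-set recovery-AUC scoring
    with group-mean enrichment tables, Wilcoxon rank-sum marker genes and
    pairwise group tests, cross-dataset cell-type similarity by ridge
    logistic regression with cross-validated penalty and iteration
    averaging, and a spot-neighborhood colocalization statistic for
    spatial prediction-score channels.  Includes seeded synthetic-data
    generators with the statistical structure the analysis assumes, so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    glmnet,
    methods,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
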