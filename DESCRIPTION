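Package: stemscore
Title: One-Class Logistic Regression Stemness Scoring for Single-Cell and Spatial Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a one-class logistic regression (OCLR) signature model on
    reference stem-cell expression profiles and scores individual cells or
    spatial spots by the Spearman correlation between the per-gene model
    weights and each cell's expression, min-max scaled to a [0,1] stemness
    index. Supports 10x-style Matrix Market and dense-table input, the
    standard single-cell QC and log-normalization steps, refitting the model
    on restricted feature panels (targeted probe or antibody panels),
    quartile stratification with Wilcoxon rank-sum differential expression
    and Bonferroni correction, marker-set cluster annotation, bootstrap
    stability analysis, and a synthetic-cohort generator with known per-cell
    stemness ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
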