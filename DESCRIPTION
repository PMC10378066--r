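Package: ecangio
Title: Angiogenic Factor Expression Analysis and Grade Modelling in
    Endometrial Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired tumour/adjacent-tissue expression
    of angiogenic factor genes in endometrial cancer. Covers
    efficiency-corrected qPCR relative quantification with reference-gene
    normalisation, signed fold-regulation statistics with paired Wilcoxon
    tests and Sidak multiplicity correction, Spearman co-expression
    screening with exact small-sample p-values, a gamma-CDF
    cross-platform harmonisation for merging cohorts measured on
    different scales, a stratified merge/split protocol, and binary
    tumour-grade classification with cross-validated model selection and
    confusion-matrix inference. Includes a synthetic paired-cohort
    generator so every stage is testable without patient material.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    fitdistrplus,
    glmnet,
    ranger,
    xgboost,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
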