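Package: senskin
Title: Senescent-Cell Scoring and T-Cell Composition Analysis for Skin scRNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify senescent-cell accumulation in multi-donor
    single-cell RNA-seq cohorts and relate it to T-lymphocyte composition.
    Implements MAD-based cell quality control, library-size log-normalization,
    derivation of cell-type-specific senescence gene signatures from
    young/old expressing-fraction criteria, per-cell senescence scoring,
    senescent-cell calling via a one-dimensional Gaussian-mixture decision
    boundary, donor-level T-subset composition statistics with Spearman and
    Bonferroni correlation scans, Mann-Whitney differential expression with
    expression-fraction filters, and hypergeometric over-representation
    analysis against GMT gene-set collections. Includes a negative-binomial
    synthetic-cohort generator with known ground truth so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
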