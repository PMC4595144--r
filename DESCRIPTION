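Package: dcoex
Title: Case-Control Blood Transcriptome Differential Co-Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end case-control analysis of blood microarray expression
    profiles: sample and probe quality control (principal-component outliers,
    sex concordance, duplicate detection, lab-quality filters, quantile
    normalization), surrogate-variable adjustment, per-probe logistic
    differential expression with two-stage replication and candidate-gene
    lookup, Spearman-based weighted co-expression networks with fixed-cut
    module extraction, co-differential co-expression permutation tests,
    differential co-expression via the dispersion statistic with
    label-permutation inference and Bonferroni correction, Z-summary module
    preservation, four-criterion hub-gene scoring, and nearest shrunken
    centroid disease classification with cross-validated shrinkage. Includes
    a synthetic-data generator that plants known co-expression modules,
    differential co-expression, covariate effects and quality-control
    failures so every stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
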