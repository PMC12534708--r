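Package: ternarycode
Title: Ternary-Code DNA Methylation Analysis for Paired 5modC/5hmC Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for paired total-modification (5modC) and
    5-hydroxymethylcytosine (5hmC) Infinium-style beta-value matrices.
    Decomposes matched profiles into the ternary cytosine code (5mC, 5hmC,
    unmodified C), discovers one-vs-rest differentially methylated CpG
    markers by Wilcoxon/AUC/delta-beta screening, performs reference-based
    cell-type deconvolution by robust partial correlations with a
    non-negative least-squares cross-check, imputes missing legacy-platform
    probes from cross-platform nearest neighbors, runs per-CpG linear EWAS
    with age/sex/tissue covariates, trains elastic-net age clocks by
    leave-one-out cross-validation with in-fold feature selection, scores
    sample sex, and provides probe-set and genomic-interval enrichment
    statistics. A synthetic-data module generates beta matrices with full
    ground truth (planted markers, Dirichlet mixtures, age and sex effects,
    a bounded 5hmC layer, replicate probes, and a two-platform split) for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    data.table,
    MASS,
    glmnet,
    pracma,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
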