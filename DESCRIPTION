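Package: ctxneu
Title: Context-Dependent Neutrophil States and Expression-Based Malignancy
    Calling in Multi-Tissue Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for multi-tissue tumor single-cell RNA-seq
    with a focus on neutrophil biology in gallbladder cancer. Implements
    cell-level quality control with consensus doublet voting, expression-based
    copy-number profiling by genomic sliding windows with a mean-of-squared-
    windows malignancy score, a bimodal likelihood-ratio differential
    expression test, construction of three context-dependent neutrophil
    activation scores by cross-tissue DEG intersection, tissue-preference
    statistics (ratio of observed to expected cell numbers), data-driven
    gene-signature construction and scoring, and a negative-binomial
    multi-tissue simulator with planted gene programs, copy-number segments,
    doublets and damaged cells for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    scran,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    Seurat,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
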