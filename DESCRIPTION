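Package: episig
Title: Discovery and Classification of Blood DNA Methylation Episignatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for discovering disorder-specific DNA methylation
    episignatures from genome-wide methylation arrays and classifying new
    samples against them. Starting from a beta-value matrix and sample
    metadata it performs probe-level quality control, beta-to-M
    transformation, reference-based blood cell-type deconvolution
    (constrained projection), cell-composition-adjusted differential
    methylation with empirical-Bayes moderated t-statistics, a three-step
    feature selection (effect-size/p-value product, AUROC, correlation
    pruning), unsupervised validation by Ward clustering, classical
    multidimensional scaling and leave-one-out cross-validation, a linear
    support vector machine emitting calibrated methylation variant
    pathogenicity (MVP) scores, and differentially methylated region
    detection by Fisher's combined probability over positional probe runs.
    A synthetic-cohort generator with known ground truth makes every stage
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    e1071,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    MASS,
    rtracklayer,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
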