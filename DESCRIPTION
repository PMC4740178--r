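Package: methfield
Title: Detection of Stochastic DNA Methylation Field Defects in Normal Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical toolkit for detecting stochastic DNA-methylation
    field defects in histologically normal tissue from Illumina 450k-style
    beta-value matrices. Implements the iEVORA two-stage differential
    variability feature-selection algorithm (Bartlett screen at stringent
    FDR followed by t-statistic re-ranking), reference-based cell-fraction
    deconvolution by constrained projection, per-sample outlier z-deviation
    calling with binarized hit matrices, Monte-Carlo permutation analyses of
    stochasticity, heterogeneity and coordination, progression and
    personalized deviation scores, and Fisher-test set enrichment. A
    synthetic-cohort module generates outlier-contaminated beta matrices
    with ground truth so the whole pipeline is testable without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
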