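Package: parasnail
Title: Parallel Ecotype Divergence Analysis for Expression and Array-CGH Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Joint analysis of gene-expression divergence and coding-sequence
    divergence (array comparative genomic hybridization) between replicate
    ecotype pairs sampled in several localities. Provides a synthetic
    probe-level data generator with known ground truth, RMA-style
    preprocessing (empty-spot background thresholds, probe filters, normexp
    background correction, single- and two-channel quantile normalization,
    median-polish summarization), row-wise linear models with empirical-Bayes
    variance moderation, the SGoF sequential binomial multiple-testing
    correction, an exact three-way gene-set intersection null with its
    permutation counterpart, directionality and intrapopulation-variance
    randomization tests, geographic-differentiation enrichment by
    resampling, and a pipeline orchestrator producing tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    limma,
    matrixStats,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
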