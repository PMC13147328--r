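Package: adductQC
Title: Preprocessing, Signal-Drift Correction and Quality Metrics for
    Untargeted DNA Adductomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-peak-picking workflow for untargeted LC-MS DNA adductomics
    feature tables: missingness filtering, half-minimum uniform imputation,
    DNA-concentration correction, six normalization / signal-drift-correction
    strategies (TIC, median, bracketing-QC FBSC-B, local-mean lomec,
    linear-model LMBSC, and QC-based robust LOESS correction with
    GCV-selected span), between-batch mean-response alignment, robust
    quality metrics (RSD* and D-ratio) with threshold-based feature
    retention, nonparametric method-comparison tests (Durbin-Conover,
    Dunn's all-pairs, Holm adjustment), advisory estimation of upstream
    peak-picking parameters from extracted ion chromatograms, and a seeded
    run-sequence simulator with ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: MassSpectrometry, Metabolomics, QualityControl, BatchEffect,
    Normalization, Preprocessing
RoxygenNote: 7.3.3
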