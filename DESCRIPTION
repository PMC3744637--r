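Package: rmxprep
Title: Optimally Robust Radius-Minimax Estimators for Expression Data Preprocessing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Optimally robust radius-minimax (rmx) k-step estimators for the
    normal location-scale model, deployed in two gene-expression summarization
    pipelines: a MAS 5.0 variant for Affymetrix PM/MM probe-level data and a
    bead-type summarizer for Illumina bead-level data. Includes the classical
    comparators (Tukey biweight one-step, skipped mean/SD, maximum likelihood),
    a minimum Kolmogorov distance module for assessing adequacy of the normal
    model, and a Monte-Carlo engine for robustness studies under gross-error
    contamination.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
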