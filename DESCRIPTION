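Package: metabnet
Title: QC Filtering, Drift Correction, Differential Abundance and
    Microbe-Metabolite Co-Occurrence Networks for Untargeted Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for untargeted LC-MS metabolomics
    studies with paired shotgun-metagenomics profiles. Implements QC-pool
    based feature filtering (dilution-series correlation, QC repeatability,
    blank ratio), LOESS correction of injection-order signal drift,
    log2 median-centering normalization, multivariate-normal EM imputation
    of left-censored missing values, an empirical-Bayes moderated t-test
    with adaptive Benjamini-Hochberg control using the Pounds robust pi0
    estimator, and permutation-tested species-metabolite co-occurrence
    networks exported as GraphML/SIF for Cytoscape. Ships a synthetic-data
    generator emulating QC pools, dilution series, blanks, multiplicative
    drift, intensity-dependent missingness, planted fold changes and
    planted microbe-metabolite correlations, so the full pipeline is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
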