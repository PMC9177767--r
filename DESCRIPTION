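Package: monekit
Title: Statistical Analysis of Deep-Image Features as Morphological Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats per-slide summaries of convolutional network image
    features ("mones", morphological genes) like gene-expression values and
    provides the statistical toolkit that view enables: tile-to-slide median
    aggregation, frequentist differential-feature tests with
    Benjamini-Hochberg control, closed-form optimal Bayesian filter (OBF)
    marker posteriors with minimal-risk and FDR-based selection, structured
    multi-group OBF for preparation artifacts, Ledoit-Wolf shrinkage
    correlation networks with Fisher-transform significance and differential
    correlation, patient-level cross-validated linear classifiers (multi-class
    LDA and L1 multinomial logistic regression), and integrative
    feature-gene-expression correlation analysis. A synthetic cohort
    generator with known ground truth supports calibration and recovery
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    igraph,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rtsne,
    arrow,
    yaml,
    optparse
Config/testthat/edition: 3
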