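Package: plasmapeaks
Title: Whole-Plasma MALDI-TOF Peptidome Fingerprinting and Immune-State
    Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for stratifying samples from
    whole-plasma MALDI-TOF linear-mode peptidome spectra (2-20 kDa).
    Covers preprocessing (square-root variance stabilisation,
    Savitzky-Golay smoothing, SNIP baseline estimation), MAD-based
    signal-to-noise peak detection, divisive peak binning into a
    sample-by-peak matrix, replicate averaging and occurrence filtering,
    presence/absence dichotomisation, feature ranking by binary
    discriminant analysis t-scores or random-forest importance,
    binary-distance hierarchical k-means clustering with PCA and cluster
    homogeneity/coverage metrics, and supervised evaluation of Bernoulli
    discriminant and random-forest classifiers with stratified train/test
    splits and repeated k-fold cross-validation. A synthetic spectrum
    generator produces three-group datasets with planted peak signatures
    so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
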