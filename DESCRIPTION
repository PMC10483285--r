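Package: neurofuse
Title: Hybrid EEG and fNIRS Feature Pipelines for Resting-State Depression Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs resting-state brain markers of major depressive
    disorder from simultaneous EEG and functional near-infrared spectroscopy
    (fNIRS) recordings and classifies subjects from them. Provides
    phase-locking-value functional networks with graph-theoretic summaries
    (clustering coefficient, path length, efficiencies, transitivity,
    modularity) integrated over a proportional-threshold sweep,
    inter-hemispheric spectral asymmetry scores, oxygenated-haemoglobin sample
    entropy, region-of-interest connectivity and laterality features, LASSO
    feature selection, and a linear support-vector machine evaluated by
    leave-one-out cross-validation. A seeded synthetic-cohort generator with
    planted group effects makes the whole pipeline testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    signal,
    glmnet,
    e1071,
    pROC,
    generics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
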