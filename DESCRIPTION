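Package: adhdconn
Title: Simulated Resting-State Connectivity and Ensemble Diagnosis of ADHD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying automated diagnosis of attention deficit
    hyperactive disorder (ADHD) from resting-state functional MRI. Provides a
    synthetic cohort generator that reproduces the statistical structure of the
    ADHD-200 sample (site-imbalanced subtype prevalence, IQ missingness,
    subtype-dependent motor-network inter-parcel correlations, low-frequency
    BOLD-like signals with drift, and peripheral high-variance motion voxels);
    temporal preprocessing (polynomial detrending, band-pass filtering,
    nuisance regression); motor-network parcel and 264-seed connectivity
    features; CUR-decomposition leverage-score voxel selection with a
    covariance feature vector and a peripheral-localization motion diagnostic;
    random-forest and two-stage gradient-boosting classifiers combined by
    majority vote with a designated tie-breaker; the hierarchical competition
    scoring metric with binary diagnostic summaries; and multinomial and
    logistic association models relating inter-parcel correlations to
    diagnosis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    nnet,
    randomForest,
    xgboost,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
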