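Package: sparecg
Title: Symmetric Projection Attractor Reconstruction for ECG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms quasi-periodic physiological signals (principally
    single-lead ECG) into two-dimensional attractors via Takens delay
    embedding and symmetric harmonic projections, extracts normalised
    radial and angular density features from the attractor point cloud,
    and evaluates case/control classifiers (k-nearest-neighbour and
    decision-tree) with leave-one-patient-out cross-validation, Bayesian
    hyperparameter search, demographic feature normalisation, stratified
    accuracy reporting and misclassification analysis. Includes a
    synthetic multi-lead ECG generator with controllable two-class
    morphology differences, a minimal WFDB reader/writer, and a
    case/control cohort construction pipeline with age- and sex-matched
    controls.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    rpart,
    randomForest,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
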