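Package: warfdose
Title: Recurrent Neural Network Warfarin Dose Prediction and
    Anticoagulation Quality Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Individualized warfarin dose prediction from longitudinal
    anticoagulation records. Implements a dose-prediction network with a
    feedforward branch for fixed clinical covariates (age, anthropometrics,
    CYP2C9/VKORC1 genotype, comedication) and a unidirectional or
    bidirectional LSTM branch for visit sequences (previous dose, INR,
    planned interval), fused by masked max pooling; the training protocol
    (MSE loss, early stopping, patient-level ten-fold cross-validation,
    sequential hyperparameter sweeps, repeated final trainings with
    fit-statistic model selection); the full prediction-evaluation suite
    (tolerance-band dose/INR accuracy with over/under classification,
    stable-dose detection and accuracy, per-visit accuracy, genotype
    sensitivity subgroups, genotype ablation, error-distribution
    summaries); Rosendaal linear-interpolation time-in-therapeutic-range
    and INR-proportion endpoints; and a seeded pharmacokinetic/
    pharmacodynamic virtual-patient simulator producing longitudinal
    cohorts with genotype-dependent dose sensitivity, delayed INR response
    and irregular clinician-driven follow-up.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
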