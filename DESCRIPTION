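Package: cufflessbp
Title: Cuffless Blood-Pressure Estimation from Synchronized ECG and PPG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for cuffless blood-pressure
    estimation from synchronized single-lead ECG and finger
    photoplethysmography (PPG). Provides a synthetic cohort generator with
    known ground truth (three-component pulse-wave morphology, a monotone
    pulse-transit-time to blood-pressure coupling, and noisy cuff
    references), pulse-wave fiducial-point detection (foot, maximum
    upstroke, systolic ejection peak, reflected and diastolic peaks),
    forward/backward pulse decomposition, feature extraction (pulse transit
    time, log-amplitudes, augmentation and perfusion indices, spectral band
    powers), linear-regression calibration with cross-validated forward
    feature selection, and an agreement/validation layer with Bland-Altman
    statistics, Spearman correlation, subgroup error analysis,
    hypertension-classification metrics with DeLong confidence intervals,
    and a Clarke-style zonal error grid.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    pROC,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
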