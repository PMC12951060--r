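Package: pulseharmonics
Title: Inter-Hand Pulse Wave Harmonic Analysis for Coronary Lesion Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying left-right asymmetry of finger
    photoplethysmography (PPG) pulse waveforms as a noninvasive marker of
    coronary artery lesion complexity (SYNTAX score >= 22). Provides a
    seeded synthetic two-hand PPG cohort generator, beat segmentation,
    per-beat Fourier harmonic decomposition into orders 0-11 with
    amplitude (Cn), phase (Pn) and energy (Dn) indices and their
    coefficients of variation, inter-hand difference features,
    sex-stratified logistic regression with forward/backward/stepwise
    AIC model selection, and internal validation by ROC/AUC,
    Hosmer-Lemeshow calibration and bootstrap resampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
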