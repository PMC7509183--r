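Package: pulsebp
Title: Cuff-Less Beat-to-Beat Blood Pressure Estimation from ECG and PPG
    During Arrhythmias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Beat-to-beat systolic and diastolic blood pressure estimation
    from synchronous single-lead ECG and finger photoplethysmogram (PPG)
    signals in arrhythmia patients, with invasive arterial pressure as the
    per-cycle reference.  Provides fiducial-point detection on ECG, PPG and
    arterial pressure waveforms, extraction of fifteen transit-time, slope,
    area and shape features per cardiac cycle, a per-beat PPG energy quality
    filter, per-patient regression models (decision tree, RBF support vector
    regression, AdaBoost.R2 and a 50-tree random forest) with
    validation-RMSE model selection, normalised random-forest feature
    importances aggregated across patients, and AAMI / BHS / Bland-Altman
    device-grade evaluation.  A seedable arrhythmic waveform simulator
    (sinus, premature ventricular and supraventricular beats with realistic
    beat-to-beat pressure excursions) makes the full pipeline testable
    without clinical recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    randomForest,
    rpart,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
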