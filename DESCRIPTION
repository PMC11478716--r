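Package: sleepbelt
Title: Sleep-Apnea Screening Analytics for a Wearable ECG and Breathing Belt
Version: 0.1.0
Authors@R:
    person("Sleepbelt", "Developers", email = "sleepbelt@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired wearable-belt and polysomnography
    recordings of whole-night electrocardiogram (ECG) and thoracic-excursion
    signals in suspected sleep apnea. Provides a synthetic-cohort generator
    (apnea event scheduling, PQRST-morphology ECG synthesis, excursion
    waveforms, artifact injection), segment-wise template-correlation signal
    quality filtering with physiological plausibility fallback, heart-rate and
    breathing-rate variability feature extraction (time domain and short-time
    Fourier band powers), Bland-Altman device agreement, support-vector-machine
    classification of apnea severity with ROC/AUC and leave-one-out
    cross-validation, and multi-night repeatability via random-intercept mixed
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    matrixStats,
    optparse,
    quadprog,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
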