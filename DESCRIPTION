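Package: skillfuse
Title: Multimodal EEG and Eye-Tracking Classification of Surgical Skill
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Subject-independent classification of surgical skill from
    synchronized electroencephalography (EEG, 512 Hz) and eye-tracking
    (50 Hz) recordings of robot-assisted vesico-urethral anastomosis
    subtasks. Provides a seeded synthetic cohort generator emulating the
    study design (class-dependent frontal theta and occipital alpha band
    power, fixation and saccade gaze dynamics, 60 Hz line contamination,
    missing gaze samples, noisy ordinal ratings from three raters); the
    full preprocessing chain (notch and band-pass filtering, common
    average reference, PCA-based artifact removal, surface Laplacian,
    gaze smoothing, spline resampling onto the EEG timeline);
    label-preserving sliding-window tensorization with zero-padding and
    step masks; a CNN-LSTM classifier with masked additive attention
    trained by class-weighted cross-entropy with early stopping; and
    grouped cross-validation, repeated held-out evaluation, confusion
    and F1 metrics, paired comparisons with Holm correction, Fleiss'
    kappa, and absolute-agreement intraclass correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    zoo,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
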