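Package: affectsig
Title: Affective State Classification from Wearable Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifies affective state (baseline, amusement, stress) from
    multi-rate wearable physiological channels (ACC, BVP, EDA, EMG, ECG, TEMP,
    RESP). Implements a per-indicator architecture: a contribution network
    scores each time window, a causal upper-triangular temporal embedding
    re-encodes windowed features so that each window depends only on the past,
    a per-indicator affect network maps the embedded features to an affect
    level, and a fusion analyser with a learnable baseline predicts the state.
    Training uses RMSprop with a composite cross-entropy plus contribution
    regularisation loss, sequential per-subject updates, and
    leave-one-subject-out cross-validation. A symbolic-distillation stage
    extracts closed-form laws per indicator via gradient-based feature
    importance and a built-in genetic-programming symbolic regression engine.
    Includes a synthetic cohort generator emulating chest- and wrist-worn
    device recordings, Butterworth denoising, window segmentation, and
    per-modality feature extraction (statistical features, HRV, electrodermal
    tonic/phasic/driver decomposition).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
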