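Package: oreeg
Title: Neural Responses to Operating-Room Soundscapes: TRF, ERP and GED Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end analysis pipeline for studying how a task-irrelevant
    operating-room soundscape is processed in mobile EEG. Provides acoustic
    feature extraction (Hilbert envelope, Wiener noise reduction, spectral-flux
    onset detection), EEG preprocessing (zero-phase FIR filtering, iterative
    bad-channel rejection, joint-probability epoch rejection, ICA artifact
    removal, spherical-spline interpolation, mastoid re-referencing),
    event-related potentials, forward temporal response functions estimated by
    lag-expanded ridge regression with segment-wise cross-validation,
    generalized eigenvalue decomposition spatial filtering of response windows,
    and a mixed-model layer (linear, Poisson and cumulative-link mixed models
    with likelihood-ratio model selection). A synthetic-data module generates
    soundscapes, letter streams, EEG with planted responses, and behavioral
    tables with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
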