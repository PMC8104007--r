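Package: oscoupler
Title: Simultaneous EEG-fMRI Band-Power Coupling and BOLD Spectral-Power Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for simultaneous EEG-fMRI coupling studies:
    in-scanner EEG artifact correction (sliding average artifact subtraction of
    gradient artifacts, QRS-locked ballistocardiogram subtraction, zero-phase
    filter chain), per-volume spectral band-power regressors (global spectral
    power and regional alpha), voxelwise parametric-modulation general linear
    models with AR(1) prewhitening and canonical hemodynamic-response
    convolution, Monte-Carlo cluster-extent multiple-comparison correction,
    and amplitude of low-frequency fluctuation (ALFF/mALFF) mapping with group
    contrasts. Includes a seeded synthetic two-group cohort generator with
    known ground-truth coupling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    RNifti,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
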