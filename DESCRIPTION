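Package: emoconn
Title: Emotion-State Segmentation from EEG Brain Connectivity and Eye
    Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking EEG functional connectivity to eye
    movement behaviour under a two-by-two valence-arousal emotion design.
    Provides an 18-channel 10-20 scalp montage with distance-based channel
    pair groups, zero-phase band filtering of the four classical EEG bands,
    a complex Morlet continuous wavelet transform for instantaneous phase
    and band power, pairwise phase-locking and signed power-difference
    connectivity with a strong/weak marking rule, distance-grouped
    connectivity eigenvalues, incremental k-means segmentation of emotional
    versus non-emotional states over time, velocity-threshold fixation and
    saccade detection with baseline-referenced pupil change, one-way ANOVA
    with Tukey HSD reporting, and a ground-truth synthetic session and
    study generator so every stage is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
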