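Package: attentionBCI
Title: Passive Attention-Aware BCI Pipeline Simulation and Evaluation
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates and evaluates a passive brain-computer interface that
    classifies internally versus externally directed attention from
    four-channel consumer EEG (Muse-style TP9/AF7/AF8/TP10 montage) and
    adapts an application by pausing its updates during internal attention.
    Provides a labeled synthetic EEG session generator (raw signal or 10 Hz
    band-power frames, with stream-corruption options), Hamming-window FFT
    band-power feature extraction into 20-dimensional feature vectors,
    person-dependent linear discriminant calibration with k-fold
    cross-validation, a sliding majority-vote pause decision rule biased
    toward not pausing, a closed-loop adaptive-application simulator, and
    offline evaluation utilities (per-phase accuracy, bin-corrected ground
    truth, pause-block segmentation and length categories, paused-time
    percentages, correlation analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, S4Vectors, SummarizedExperiment, jsonlite,
    signal, MASS
Suggests: testthat (>= 3.0.0), withr, yaml, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
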