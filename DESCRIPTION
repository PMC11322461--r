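Package: somnus
Title: Sleep Architecture, Spindles and Circadian Rhythm Analysis for
    Rodent EEG/EMG Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for rodent polysomnography under light-dark
    entrainment and phase-restricted feeding designs. Provides a
    ground-truthed synthetic cohort generator (semi-Markov hypnograms,
    state-conditioned EEG/EMG signals with planted sigma-band spindles,
    Barnes-maze trial tables), EDF and hypnogram input/output, per-epoch
    Welch spectral features, semi-supervised vigilance-state scoring from
    a small human-labelled fraction of epochs, hypnogram architecture
    metrics (binned state amounts, bouts, brief arousals, correct-phase
    proportions), circular mean-vector rhythm statistics (peak time and
    relative amplitude), dual standard-deviation threshold sleep-spindle
    detection on a moving RMS envelope, Barnes-maze learning metrics, and
    a factorial ANOVA / Bonferroni-corrected correlation statistics layer,
    orchestrated by a reproducible end-to-end pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    signal,
    MASS,
    car,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    jsonlite
Config/testthat/edition: 3
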