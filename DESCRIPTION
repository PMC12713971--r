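Package: specscore
Title: Spectral Sleep Scoring of Single-Channel Forehead EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automatic sleep staging from a single EEG channel using
    whole-night Morlet wavelet spectrograms. The night is decomposed into
    a 0.1-100 Hz time-frequency representation, baselined against the
    whole-night spectrum (excluding noise epochs), and summarised per
    30-s epoch as five spectral band powers: Wake (gamma), REM (low
    beta), Light (sleep spindles), Hi Deep (delta) and Lo Deep (slow
    oscillations). Epochs are staged with a Gaussian-emission hidden
    Markov model refined by expectation maximization and decoded by
    maximal posterior probability, followed by rule-based corrections
    for irregular sleep expressions. Includes spindle/REM peak-frequency
    band refinement, a synthetic sleep-EEG generator with known
    hypnograms, EDF input/output, hypnogram comparison statistics
    (confusion matrices, bidirectional percentages, cross-subject
    medians, stage durations) and whole-night sleep-report figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
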