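Package: sana
Title: Synchronous Amplitude Network Analysis of Brain Rhythms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts short-timescale synchronous amplitude modulation among
    six EEG rhythms (delta, theta, alpha, sigma, beta, gamma), quantifies
    pairwise coupling through window-wise cross-correlation of smoothed
    relative band power, builds coupling distribution profiles and
    degree-of-coupling matrices, assembles dual positive/anti-correlated
    rhythm networks per physiological state, and validates them with a
    surrogate-test battery (shuffling, random-subject pairing, Fourier phase
    randomization, absolute-power control, time-scale sweeps). Includes a
    synthetic coupled-rhythm EEG generator so the full pipeline is testable
    without recorded data, plus EDF/CSV readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
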