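Package: thermoEEG
Title: Simulation and Analysis of EEG Changes Under Whole-Body Hyperthermia
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate anesthetized-mouse EEG sessions recorded during
    a controlled core-temperature ramp (37 to 42 degrees Celsius) and to analyse
    them: zero-phase bandpass filtering, session-wise 0-1 normalization, 5-s
    epoching with integer-temperature binning, per-epoch maximum peak-to-peak
    amplitude, Welch band power in the delta/theta/alpha/beta bands, linear
    amplitude-temperature regression, and two-sample permutation tests
    (Monte-Carlo and exact enumeration). A calibrated synthetic-session
    generator with a temperature-dependent signal envelope supports parameter
    recovery studies, and a study runner orchestrates the full pipeline over a
    multi-session manifest with EDF/CSV interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
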