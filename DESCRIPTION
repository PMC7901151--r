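Package: dccrig
Title: Virtual Discontinuous Current-Clamp Rig and Excitability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates intracellular current-clamp recordings through sharp
    microelectrodes in Bridge and discontinuous current-clamp (DCC) modes,
    using passive RC cell and electrode models and an integrate-and-fire
    motoneuron with an afterhyperpolarization (AHP) conductance. Provides
    closed-form steady-state predictions for chopped-current RC responses,
    stimulus protocols (triangular current ramps, square-pulse series, short
    pulses), and an analysis suite for excitability measurements: spike
    detection, frequency-current (F-I) curves, onset/offset current, F-I
    gain, voltage threshold, apparent input resistance, membrane time
    constant, membrane-potential ripple amplitude, interspike-interval
    entrainment, plateau detection, and a minimum recommended DCC switching
    rate. Quantifies how suboptimal DCC switching rates distort apparent
    resistance and firing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
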