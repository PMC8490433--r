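Package: stochsense
Title: Simulation and Kinetic Analysis of Single-Molecule Nanopore
    Stochastic-Sensing Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for single-channel stochastic sensing with programmable
    nano-reactor nanopores. Simulates telegraph-signal current traces from
    explicit continuous-time Markov kinetic schemes with state-dependent
    noise, acquisition filtering, irreversible termination and voltage-reload
    cycles; idealizes traces into event tables (blockage amplitude, dwell
    time, inter-event interval, sub-level structure); estimates association
    and dissociation rate constants and equilibrium binding constants from
    dwell-time statistics, with Arrhenius temperature fits and detection-limit
    calculations; and discriminates analyte classes from frequency-split
    noise features with a support-vector classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    e1071,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
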