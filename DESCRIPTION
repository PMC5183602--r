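Package: eiphase
Title: Phase Relationships Between Excitatory and Inhibitory Populations in
    Network Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Conductance-based spiking network model of coupled excitatory
    (pyramidal) and inhibitory (fast-spiking interneuron) populations, with
    configurable E-I-only, I-I-only and combined-loop topologies, together
    with a phase-shift measurement pipeline (population rates, oscillation
    spectra, cross-correlation lags and the four-lag cycle decomposition).
    Single-compartment Hodgkin-Huxley interneurons and two-compartment
    pyramidal cells with high-threshold Ca and Ca-activated AHP currents are
    coupled through AMPA, NMDA (with Mg block) and GABA-A receptor kinetics
    and driven by Poisson background input; integration uses a second-order
    Runge-Kutta scheme implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
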