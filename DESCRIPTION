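Package: pingmf
Title: Exact Mean-Field Analysis of PING Gamma Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying gamma-band oscillations generated by
    pyramidal-interneuron (PING) circuits of quadratic integrate-and-fire
    neurons. Provides a finite-size spiking network simulator with AMPA,
    NMDA and GABA synapses and Lorentzian (quenched) heterogeneity, the
    exact seven-dimensional mean-field reduction obtained via the
    Ott-Antonsen / Lorentzian ansatz, Welch-based gamma power and peak
    frequency metrics, one- and two-parameter Hopf bifurcation analysis
    with eigenvalue certificates, and a synergy pipeline that quantifies
    how combinations of disease-associated synaptic alterations reduce
    gamma power beyond their additive prediction.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
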