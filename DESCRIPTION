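Package: riskbn
Title: Hybrid Bayesian Network Analysis of Passenger Risk Perception
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for a within-subject driving
    study of passenger risk perception in an autonomous vehicle. Generates
    synthetic subjective-assessment (hand slider) and electrodermal traces
    for a 20-participant by 32-trial design crossing time-to-collision and
    lateral offset; preprocesses skin conductance, deconvolves phasic
    responses against a Bateman impulse response and detects skin
    conductance responses (SCRs); extracts per-manoeuvre indicators (mSA,
    iSA, nSCR, mSCR); normalises them; and selects the dependency structure
    between subjective and electrodermal risk perception by exhaustive
    scoring of 48 hybrid Bayesian networks (Gaussian and Tweedie
    compound-Poisson nodes) with a decomposed Bayesian Information
    Criterion, plus an exhaustive set-partition clustering of condition
    means. Includes a self-contained Tweedie compound-Poisson engine
    (density, zero mass, sampling, profile-likelihood GLM).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    pracma,
    jsonlite
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
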