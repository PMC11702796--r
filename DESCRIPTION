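Package: stabscan
Title: Stability Impact Scoring for Missense Mutations from Denaturation
    Curves and Replica-Exchange Thermodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how missense mutations change protein
    stability. Fits two-state thermal and chemical denaturation models to
    intrinsic-fluorescence spectra series (apparent melting temperature,
    van't Hoff enthalpy, unfolding free energy and m-value), analyses
    multi-temperature replica-exchange trajectories with the weighted
    histogram analysis method (heat capacity curves, melting temperatures,
    potential-of-mean-force landscapes, exchange-rate diagnostics),
    converts every effect to a common free-energy scale, and aggregates
    predictor, simulation, thermal and chemical contributions into a
    normalized per-mutation impact score. Includes synthetic-data
    generators with exact ground truth: two-state fluorescence spectra
    and a Metropolis-sampled Zimm-Bragg helix-coil chain with a
    transfer-matrix analytic oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
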