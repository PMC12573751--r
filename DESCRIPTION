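Package: committorlab
Title: Nonparametric Committor Estimation for Multimolecular Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to determine the committor -- the optimal reaction
    coordinate for equilibrium two-state kinetics -- from long trajectories
    of multimolecular systems. Includes a Metropolis Monte Carlo simulator
    for an anisotropic two-dimensional lattice aggregation model at
    dilute/aggregated coexistence, construction of translation-, rotation-
    and permutation-invariant collective variables via sorted distance
    matrices, iterative nonparametric variational optimization of a putative
    reaction coordinate by total-squared-displacement minimization with
    clamped boundary states, and a diffusive-model layer: histogram and cut
    free-energy profiles, a cut-profile committor validation scan over
    dyadic lags, position-dependent diffusion coefficients, unit-diffusion
    rescaling, and kinetics (mean first passage times from the 1D diffusive
    model and directly from time series, transition counts, equilibrium
    flux, mean transition-path times). Synthetic oracles (discrete Markov
    chains and 1D double-well Brownian dynamics with exactly known
    committors) support validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
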