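Package: eprinfer
Title: Entropy Production Inference from Fluctuating Currents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for inferring the entropy
    production rate of nonequilibrium steady states from trajectory data.
    Implements multi-bath bead-spring chains (overdamped Langevin dynamics
    and an equivalent continuous-time lattice jump process), analytic
    steady-state oracles (stationary covariance, probability currents,
    thermodynamic force), kernel and histogram estimation of density and
    current fields, spatial and temporal entropy production estimators,
    generalized-current statistics with thermodynamic uncertainty relation
    (TUR) lower bounds, exact current cumulants on the lattice via the
    tilted-operator scaled cumulant generating function, and Metropolis
    Monte Carlo optimization of the current weighting field.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
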