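Package: ctpdyn
Title: Multiscale Dynamics of Epigenetically Inherited Drug Persistence
Version: 0.1.0
Authors@R:
    person("ctpdyn", "authors", email = "ctpdyn@example.org", role = c("aut", "cre"))
Description: Simulates the emergence of drug-tolerant persister (DTP) and
    drug-resistant cells in a cancer cell population under cytotoxic
    treatment. A heritable epigenetic trait, the chance to persist (CTP),
    is transmitted at cell division through a Beta-distributed inheritance
    kernel whose mean shifts with drug dose, and is coupled to a
    phenotype-structured population balance model with stress-induced
    phenotype adaptation, logistic crowding and dose-gated apoptosis.
    Provides a deterministic finite-volume solver for the population
    integro-PDE, a single-cell probability-density formulation, a
    stochastic agent-based simulator, an intermittent-treatment scheduling
    engine with min-max optimization over therapeutic time and drug
    holidays, and a synthetic-data module with parameter estimation for
    clone-level CTP distributions and tumor-volume kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
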