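Package: specdcm
Title: Spectral Dynamic Causal Modelling of Resting-State Networks Across the Lifespan
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A pipeline for estimating directed (effective) connectivity among
    resting-state fMRI networks from BOLD cross-spectral densities. Implements a
    spectral dynamic causal model (linear neural coupling driven by power-law
    endogenous fluctuations, observed through a linearized balloon hemodynamic
    model), variational-Laplace inversion with free-energy model evidence,
    enumeration of biologically plausible model spaces, fixed- and random-effects
    Bayesian model selection with Bayesian model averaging, and group-level
    statistics relating connectivity parameters to age and cognition (multiple
    regression, canonical correlation analysis with structure correlations,
    moderation analysis, and a Fisher-z functional-connectivity baseline).
    Includes a seeded synthetic-cohort generator emulating a large lifespan
    resting-state study for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
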