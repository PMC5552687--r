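Package: mlpmf
Title: Multi-Level QM/MM Free-Energy Pipelines with Surrogate Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping reaction paths and composing multi-level
    potentials of mean force for a solute in explicit water. Provides
    nudged-elastic-band path optimization with climbing image and
    finite-difference frequency verification, an SPC/E-style rigid-water
    molecular-mechanics potential with Metropolis Monte Carlo sampling,
    electrostatically embedded QM/MM energy decomposition with a hard
    coupling cutoff, free-energy-perturbation (Zwanzig) level shifting of a
    cheap-level profile onto higher tiers, solvent and polarization
    decomposition of the resulting profiles, thermodynamic-cycle solvation
    estimates, and transition-state-theory rate constants. Electronic
    structure tiers are represented by pluggable analytic surrogate
    potentials so that every stage runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
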