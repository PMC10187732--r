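Package: hpsep
Title: Coarse-Grained HP Heteropolymer Simulation and Phase-Separation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator and analysis pipeline for two-letter (hydrophobic/polar)
    coarse-grained heteropolymers used as minimal models of intrinsically
    disordered proteins. Implements an Ashbaugh-Hatch scaled Lennard-Jones
    pair potential with two mixing rules (strong localized H-H attraction
    versus weak distributed H-H plus H-P attraction), Langevin dynamics of
    bead-spring chains in periodic boxes, single-chain ensemble observables
    (radius of gyration, shape anisotropy, intrachain scaling, end-to-end
    relaxation), interaction-strength calibration against a homopolymer
    reference, two-chain potentials of mean force and second virial
    coefficients, direct-coexistence slab analysis with coexistence
    concentrations, and chain cluster-size distributions for finite
    self-assembly.
License: MIT + file LICENSE
Encoding: UTF-8
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    broom,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
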