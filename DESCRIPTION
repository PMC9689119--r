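Package: frypareto
Title: Multi-Objective Design of Potato Frying Balancing Acrylamide and Colour
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Model-based design of isothermal potato-frying processes. Simulates
    acrylamide formation through a Maillard reaction network of five coupled
    ordinary differential equations (glucose, fructose, asparagine, Schiff base,
    acrylamide) with temperature-dependent rate constants, and fried-slice
    quality through first-order yellowness and moisture kinetics with power-law
    temperature correlations. Computes the constrained Pareto front between
    acrylamide (minimised) and yellowness (maximised) under a terminal moisture
    constraint, by both a complete level-curve search and an elitist
    non-dominated sorting genetic algorithm (NSGA-II), detects practically
    equivalent operating points, and propagates kinetic-parameter uncertainty
    to an ensemble of Pareto fronts by Monte Carlo. Includes a calibrated
    synthetic kinetic-parameter generator so the full pipeline is testable
    without external rate-constant tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
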