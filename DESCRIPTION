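Package: panhgt
Title: Stochastic Bacteria-Phage Coevolution with Horizontal Gene Transfer
Version: 0.1.0
Authors@R: person("panhgt", "maintainers", email = "panhgt@example.org",
    role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a minimal model of microbial
    "panimmunity": bacteria carrying small combinations of toxin/antitoxin
    defense genes coevolve with phages carrying matching antitoxin
    counter-defense genes under stochastic Lotka-Volterra dynamics, while
    horizontal gene transfer shuffles single genes between genomes.
    Provides a tau-leaping simulator over the combinatorial genotype space,
    observables (Lyapunov energy, persistence times, Gamma
    abundance-distribution fits, boom-bust peak statistics, dynamical-regime
    labels), closed-form ensemble predictions (effective temperatures,
    critical HGT rates, diversity carrying capacities), and experiment
    drivers (parameter scans, phase-boundary bisection, temperature sweeps)
    with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
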