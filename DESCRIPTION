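Package: meiodyn
Title: Dynamical Modelling of Xenopus Oocyte Meiotic Maturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a coupled MPF/MAPK/CPEB regulatory
    network model of Xenopus laevis oocyte meiotic maturation. Provides the
    13-variable ordinary differential equation model (six class-I proteins with
    active/inactive forms, Emi2 in three phosphoforms) with quasi-steady-state
    class-II kinase activities, time-course simulation under progesterone
    inputs, extraction of MPF trajectory indicators and in-silico phenotype
    classification, pseudo-arclength equilibrium continuation with saddle-node
    detection and progesterone thresholds, submodule diagnostics (bistable MAPK
    switch, MPF-APC relaxation oscillator with saddle-node-on-invariant-circle
    onset), dual parameter-sensitivity measures with network-module
    partitioning, a knockout/overexpression phenotype suite, and seeded
    Monte Carlo robustness analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
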