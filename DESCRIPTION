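Package: nafldsim
Title: Multi-Scale Simulation of Fatty-Acid-Driven Liver Disease Progression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A generic multi-scale model of free fatty acid (FFA) driven
    non-alcoholic fatty liver disease (NAFLD). The liver is represented as an
    ensemble of functionally heterogeneous liver units, each with two-pool
    FFA/triacylglycerol turnover kinetics, Poiseuille-type sinusoidal
    perfusion and damage-regeneration dynamics of the intact-hepatocyte
    fraction, coupled through a shared plasma FFA compartment. Provides
    minute-scale stiff ODE integration of diurnal lipid dynamics, a
    two-timescale quasi-steady-state scheme for multi-decade disease
    progression, virtual-patient ensembles with randomized unit parameters,
    disease observables (total fraction of intact hepatocytes, steatosis
    fraction, steatosis pattern score), and reproducible scenario presets
    with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
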