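Package: phagesector
Title: Simulation and Analysis of Phage Lysis Sector Patterns in
    Bacterial Swim Rings
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mean-field reaction-diffusion-advection model of lytic
    bacteriophages co-propagating with chemotactic host bacteria on a
    soft-agar plate. Four coupled fields (susceptible bacteria, infected
    bacteria, free phages, nutrient) evolve on a masked circular domain
    with Keller-Segel motility gated by nutrient availability.
    Includes an operator-split finite-volume solver, a well-mixed ODE
    reference integrator, pattern-analysis routines (swim-ring front
    kinematics, phage initiation zone, lysis-sector angle profile,
    boundary-shape classification, co-propagation outcome), figure-style
    scenario presets with sweep drivers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
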