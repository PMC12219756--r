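Package: cpcset
Title: Phase-Field Simulation of Calcium-Phosphate Cement Setting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the setting of injectable calcium-phosphate cement
    paste with an Allen-Cahn type phase-field model whose diffusion
    coefficient switches off at the initial-setting time. Provides the
    reaction kinetics with an IP6-concentration-dependent solid-formation
    threshold, a method-of-lines finite-difference solver (5-point Neumann
    Laplacian, classical fourth-order Runge-Kutta), seeded noisy initial
    conditions, nondimensionalizing scale transforms, void/fragmentation
    metrics on order-parameter fields, and reduction of Vicat needle
    penetration curves to setting times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
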