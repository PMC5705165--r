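Package: actomotion
Title: Free-Boundary Actomyosin Model of Lamellipodial Cell Motility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a minimal free-boundary model of lamellipodial cell
    motility: a myosin advection-diffusion equation coupled to an elliptic
    force balance for the actin flow on a moving two-dimensional domain, with
    zero-velocity (ZV) or zero-stress (ZS) boundary conditions and a no-flux
    Rankine-Hugoniot condition for myosin at the moving edge. Provides a
    mass-conservative cut-cell finite-volume discretization on a Cartesian
    background grid, marker-based front tracking with periodic-spline
    resampling, a segregated fixed-point time stepper validated against a
    fully coupled reference solver, one-dimensional linear stability analysis
    (dispersion relation and critical contractility), manufactured-solution
    convergence benchmarks, and trajectory analytics that classify the
    asymptotic motility state (stationary, translation, rotation) and drive
    phase-diagram parameter scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    generics,
    stats,
    utils,
    yaml,
    rlang,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
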