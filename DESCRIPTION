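Package: cmtkin
Title: Center-Manifold Stability Analysis of Nonlinear Protein-Assembly
    Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for a three-species kinetic model of cofactor-driven
    protein (tubulin/actin-like) polymerization in which monomer diffusion
    coefficients depend on the concentration fluctuations themselves,
    making the fluctuation dynamics nonlinear.  The package computes exact
    steady states, the Jacobian of the two-dimensional fluctuation system,
    eigenvalue regime classification, the critical cofactor concentration
    at which the Jacobian determinant vanishes, and deterministic
    trajectories of the attenuating/oscillating/diverging fluctuation
    regimes.  A small exact symbolic engine (multivariate rational-function
    arithmetic) performs the center-manifold reduction at the critical
    point: suspension of the bifurcation parameter, eigenbasis transform,
    order-by-order solution of the invariance equation, reduced dynamics on
    the manifold, and the fixed-point branches exhibiting the bifurcation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
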