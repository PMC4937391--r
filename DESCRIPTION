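Package: retractsim
Title: Hyper-Viscoelastic XFEM Simulation of Surgical Brain Retraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the discontinuous soft-tissue deformation caused by
    surgical brain retraction. An Ogden-type hyper-viscoelastic constitutive
    model with Prony-series stress relaxation is discretised with the extended
    finite element method (XFEM) on an octree hexahedral mesh, where a
    two-level-set crack representation and Heaviside/crack-tip nodal
    enrichment capture the tissue discontinuity opened by the retractor
    blades. Displacement boundary conditions are recovered from tracked
    retractor-surface point clouds by coherent point drift registration; the
    solved deformation field drives a crack-aware backward warp of the
    pre-retraction image into a predicted post-retraction image. Includes a
    deterministic phantom generator, registration-accuracy metrics (forecast
    error, prediction accuracy, Dice overlap, target registration error) and
    a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
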