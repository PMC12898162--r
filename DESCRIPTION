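Package: innerpot
Title: Ion-Induced Inner Potential and Membrane Electroporation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for how electrolyte ions modulate membrane
    electroporation under an applied electric field. Provides an overdamped
    Langevin (Brownian dynamics) generator of synthetic electrolyte/membrane
    trajectories with electrophoretic drift and an impermeable membrane slab;
    particle-to-grid charge assignment (nearest-grid-point and cloud-in-cell);
    a spectral (FFT) Poisson solver under full periodic boundary conditions
    that turns the time-averaged ionic charge density into the ion-induced
    inner electrostatic potential; transmembrane water-chain pore detection
    with censoring; electrophoretic ion kinematics (unwrapping, drift,
    surface accumulation, charge concentration); and a reproducible
    simulate-grid-solve-detect-report pipeline with GRO/XYZ, Gaussian cube
    and TSV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
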