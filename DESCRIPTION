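Package: ipetdna
Title: Individual-Particle Electron Tomography of DNA-Nanogold Conjugates
Version: 0.1.0
Authors@R:
    person("IPET", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for individual-particle electron
    tomography (IPET) of double-stranded DNA end-labelled with gold
    nanoparticles. Generates worm-like-chain DNA conformations and synthetic
    tilt series, performs ab-initio iterative translational projection-matching
    reconstruction with Fourier shell correlation and signal-to-noise
    diagnostics, measures gold-particle diameters and centre-to-centre
    distances in 2D and 3D, traces the inter-gold DNA centerline in density
    maps, fits smooth curve models, and computes worm-like-chain bending
    angles, energies and persistence-length estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    splines,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
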