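Package: gridtorus
Title: Toroidal Decoding and Reference-Frame Analysis of Grid-Cell Modules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for monitoring path integration in medial entorhinal
    grid-cell modules. Classifies grid cells from occupancy-normalized rate
    maps and spatial autocorrelations, fits a three-axis cosine grid model to
    instantaneous firing rates, maps trajectories onto the module's toroidal
    state space, decodes toroidal position from population spiking with a
    recurrent (LSTM) network, reconstructs movement vectors, and quantifies
    reference-frame anchoring (room landmark versus movable object) with
    bivariate von Mises concentration statistics, orientation-drift measures
    and drift-versus-homing circular correlations. Includes a synthetic
    session generator (foraging and homing-task trials, inhomogeneous Poisson
    spiking, configurable reanchoring and orientation drift) so the whole
    pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
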