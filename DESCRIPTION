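Package: gridcan
Title: Grid-Cell Continuous Attractor Networks with Heterogeneities and
    Resonator Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of rate-based continuous attractor
    network (CAN) models of medial entorhinal grid cells on a toroidal
    lattice. Supports virtual open-field trajectories, graded intrinsic,
    afferent and synaptic heterogeneities, and three single-neuron
    dynamics (leaky integrator, phenomenological high-pass resonator and
    mechanistic slow-negative-feedback resonator). Provides
    occupancy-normalised rate maps, rotational grid scores, spatial
    information and sparsity, single-neuron chirp characterisation of
    intrinsic resonance, spectral comparison of heterogeneous networks
    against homogeneous twins with octave-band summaries, and
    reproducible experiment presets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
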