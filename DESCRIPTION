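Package: spinalmcm
Title: Motion Correction and Quantification for Long-Term Spinal Cord
    Fluorescence Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for one-photon fluorescence imaging of the spinal cord in
    awake, behaving mice. Implements a hierarchical motion-correction workflow:
    feature-based large-displacement rigid correction from tracked vasculature
    control points (LD-MCM), non-rigid correction with axis-constrained
    diffeomorphic demons displacement fields (NR-MCM), and cross-session
    alignment with cell matching (CS-MCM). Also provides the surrounding
    quantification stack: movie preprocessing (detrending, spatial bandpass
    division, delta-F-over-F, downsampling), Frangi-vesselness blood-vessel
    diameter measurement via per-frame local thickness, locomotor speed from
    quadrature encoders and pose tracks, von Frey mechanical thresholds,
    microglial asymmetry ratios, stimulus response maps, and a synthetic
    spinal-cord movie generator with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    tiff,
    rhdf5,
    EBImage,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
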