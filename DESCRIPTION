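Package: mesochrom
Title: Mesoscale Heterochromatin Domains from Polymer Simulation and Soft
    X-Ray Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study the mesoscale organization of heterochromatin
    from two directions. A Brownian-dynamics simulator of a confined
    two-type (euchromatin/heterochromatin) bead-spring polymer with a
    tunable heterochromatin affinity, together with its dynamical and
    structural observables (mean squared displacement, overlap function,
    confinement-corrected pair correlation, cluster identification and
    cluster coordination numbers). A quantification pipeline for
    cryo-soft-X-ray tomography linear-absorption-coefficient (LAC)
    volumes: thresholding, watershed segmentation of mesoscale domains,
    missing-wedge corrected effective diameters, nearest-neighbour and
    pair-correlation statistics, coordination numbers, and skew-normal
    size-distribution fits. Supporting components include a toy parallel
    beam tilt-series forward model with SIRT reconstruction and Fourier
    shell correlation resolution estimation, mask-based 2D isotropic
    affine registration, a PCA-LDA / random-forest multiparametric
    classification stage, and synthetic-data generators that emulate the
    statistical structure of the real data so that every pipeline stage
    is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    igraph,
    randomForest,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
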