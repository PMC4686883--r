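Package: pipetteAim
Type: Package
Title: Image-Guided Adaptive Micropipette Positioning for Single-Cell
    Targeting
Version: 0.9.0
Authors@R: person("Alex", "Devlin", email = "alex.devlin@example.org",
    role = c("aut", "cre"))
Description: Tools for three-dimensional image-guided targeting of single
    cells with a glass micropipette under two-photon volumetric microscopy.
    Provides automatic pipette-tip localization from smoothed
    maximum-intensity projections, soma detection with an anisotropy-aware
    3D Gaussian bandpass (difference-of-Gaussians) filter, geometric
    planning of approach trajectories along the pipette axis, adaptive
    mid-course trajectory correction compensating pipette deflection and
    target-cell displacement, a synthetic two-channel fluorescence phantom
    generator with ground truth for closed-loop simulation, and summary
    statistics of approach precision (lateral/axial separation
    decomposition).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'evaluation.R'
    'filters.R'
    'geometry.R'
    'io.R'
    'localization.R'
    'manipulator.R'
    'phantom.R'
    'pipetteAim-package.R'
    'segmentation.R'
    'simulate.R'
    'trajectory.R'
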