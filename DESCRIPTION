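Package: gaitkin
Title: Automated Limb Kinematics from Markerless Pose Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying rodent locomotion from 2D markerless
    pose-estimation output. Segments treadmill stride cycles from toe
    trajectories, computes 44 per-cycle kinematic parameters in five
    categories (joint angles, limb endpoint trajectories, temporal gait
    features, spatial variability via dynamic time warping, and dragging),
    detects and scores footfalls on ladder-rung crossings by peak
    prominence, and provides downstream per-cycle random-forest
    classification and principal component analysis with factor loadings.
    Includes a synthetic trace generator with known ground truth for
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'gaitkin-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'pose-io.R'
    'synthetic.R'
    'kinematics.R'
    'parameters.R'
    'footfalls.R'
    'analysis.R'
    'cli.R'
    'plots.R'
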