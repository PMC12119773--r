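Package: scintigrade
Title: Automated Detection and Grading of Cardiac Amyloid Uptake on Planar Scintigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis pipeline for automated detection and
    Perugini-style severity grading of cardiac transthyretin amyloidosis
    (ATTR-CM) on total-body planar bone scintigraphy. Provides a digital
    phantom generator with graded left-ventricular tracer uptake and Poisson
    counting noise, pseudo-planar projection of 3D activity volumes,
    percentile-based intensity normalization, explainable uptake augmentation,
    trainable 2D segmentation with sliding-window inference, mask-driven
    region cropping with physical-unit margins, multi-crop multi-view binary
    classification with patient-wise cross-validation, two-stage
    probability-averaging ensembling, a full classification metric suite,
    and GradCAM / occlusion-sensitivity interpretability maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'scintigrade-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'utils.R'
    'augment.R'
    'ensemble.R'
    'preprocess.R'
    'engine.R'
    'classification.R'
    'explain.R'
    'io.R'
    'localization.R'
    'phantom.R'
    'segmentation.R'
    'projection.R'
    'pipeline.R'
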