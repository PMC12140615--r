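Package: mindyscapes
Title: Individualized Neural-Mass Network Models and Their Attractor Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits individualized nonlinear neural-mass network models (the MINDy
    parameterization: sparse plus low-rank effective connectivity, region-specific
    curvature and decay) to parcel-averaged resting-state fMRI timeseries, and
    characterizes each model's attractor landscape. Provides hemodynamic
    deconvolution and derivative-target preprocessing, minibatch NADAM fitting of
    the regularized one-step prediction loss, numerical detection and clustering of
    stable equilibria and limit cycles, ghost-attractor extraction, bifurcation
    probing by convex combination of model dynamics, an analytic
    infinite-period (SNIC) toy model, dominant-attractor-similarity reliability
    analysis, cosine K-means clustering with an instability-based choice of K, and
    a synthetic-data module generating all inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'model_core.R'
    'preprocess.R'
    'fit.R'
    'attractors.R'
    'bifurcation.R'
    'reliability_cluster.R'
    'synthetic_data.R'
    'io.R'
    'pipeline.R'
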