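Package: movenc
Title: Movement Encoding Models for Visual Cortex Spiking Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to ask how much of visual-cortex spiking activity is
    driven by an animal's own spontaneous body and face movements. Implements
    motion-energy decomposition of behavioral video by temporal-segment SVD,
    construction of ridge-regression design matrices with one-hot stimulus
    kernels, event kernels, drift tent bases and tent-convolved analog
    movement and eye regressors, per-unit ridge fits with trial-blocked
    tenfold crossvalidation, shuffle-in-time unique-variance partition split
    by retinal-input epochs, stimulus-matched movement and attention
    modulation indices, paired permutation tests, and a synthetic-session
    generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    knitr
Config/testthat/edition: 3
biocViews: Software, Electrophysiology, Regression, StatisticalMethod
RoxygenNote: 7.3.3
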