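Package: mrcpDecode
Title: Single-Trial Decoding of Hand-Grasp Kinetics and Types from Premovement EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for decoding task-related parameters (grasp type, force and
    speed of contraction) from single-trial premovement EEG. Implements
    movement-related cortical potential (MRCP) component features (readiness
    potential, negative slope, peak negativity) and band-power features of the
    classical EEG rhythms, Mann-Whitney u-statistic ranked sequential forward
    selection with one-vs-rest candidate sets and a merge-and-reselect round,
    regularized linear discriminant and linear support-vector classification
    under stratified k-fold and leave-one-subject-out cross-validation,
    binomial theoretical chance levels, and selection-frequency feature and
    channel importance. Ships a synthetic EEG/force generator that emulates
    cued grasp experiments (MRCP morphology, class-dependent rhythm power, 1/f
    background, blink artifacts, force ramps) so the whole pipeline is
    testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    data.table,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
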