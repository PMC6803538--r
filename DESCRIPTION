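Package: neurointent
Title: Bimodal EEG-fNIRS Synthesis, Brain-Network Features and Intention Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates bimodal EEG and functional near-infrared spectroscopy
    (fNIRS) recordings of a three-condition action-observation paradigm with
    known ground truth, and provides the full analysis pipeline for such data:
    band-pass/notch filtering, regression-based ocular artifact removal,
    modified Beer-Lambert conversion of optical intensities to hemoglobin
    concentration changes, epoching and baseline correction, channelwise
    ANOVA and block t-tests with topographic maps, a lagged cross-correlation
    analysis of neurovascular coupling between event-related potentials and
    oxyhemoglobin waveforms, per-trial functional connectivity networks with
    five nodal graph metrics, and three-class intention decoding with
    Relief-F feature selection and a grid-searched RBF support vector
    classifier under repeated stratified cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    signal,
    e1071,
    mgcv,
    yaml,
    jsonlite,
    data.table
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
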