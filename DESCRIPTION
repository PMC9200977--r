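Package: pupilperim
Title: Chromatic Pupilloperimetry Analysis of the Pupillary Light Reflex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of chromatic pupilloperimetry recordings.
    Provides a synthetic cohort generator for transient and sustained pupil
    light reflex (PLR) traces on the 54-target 24-2 visual-field grid,
    extraction of 17 kinetic PLR parameters per target (amplitudes,
    velocities, accelerations and latencies of the contraction and
    redilation phases), per-parameter AdaBoost classification of
    family-history status, stratified bootstrap out-of-bag AUC-ROC
    confidence intervals with per-target feature-weight maps, and focal
    group comparisons of pupil response latency with age adjustment and
    Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    signal,
    jsonlite,
    Rcpp,
    SummarizedExperiment,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
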