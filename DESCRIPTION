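Package: streetnav
Title: Simulation and Analysis of Bimanual Cursor Street-Navigation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing bimanual motor-learning
    experiments in which participants steer a cursor along straight and
    curved street corridors using two keys, one per hand. Provides the task
    geometry (angle grids, balanced pseudo-random schedules, curved transfer
    streets and their axis transpositions), a frame-based simulator of the
    two-key acceleration control law with wall-collision resets, a synthetic
    participant model with exponential learning and a bimanual-competence
    covariate, the speed-accuracy performance index (PI) with pilot-based
    normalisation, trial-difficulty denoising by regression, and the study
    statistics: ANOVA/ANCOVA with partial eta squared, Bonferroni follow-up
    t-tests, Pearson correlation of training and transfer change, and
    noncentral-F power planning for repeated-measures between-factor designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    data.table,
    car,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
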