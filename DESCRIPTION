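Package: svvbias
Title: Visuo-Vestibular Modelling of Verticality Perception Under Visual Noise
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis pipeline for subjective-visual-vertical
    (SVV) experiments in which a rotating annulus of dots biases perceived
    vertical. Implements a velocity-storage internal model of visuo-vestibular
    head-rotation estimation with somatogravic feedback, a velocity-preserving
    random-dot noise stimulus generator, band-limited bar-position noise, a
    synthetic behavioural-data generator (bar-angle trials and two-alternative
    forced-choice velocity judgments), the behavioural data reduction (rebasing,
    direction folding, window means, exponential rise fitting), random-intercept
    mixed-model inference with likelihood-ratio tests, point-of-subjective-
    equality extraction from psychometric grids, and sum-of-squared-error
    fitting of the mechanistic model to condition-mean bias traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    minpack.lm,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    knitr,
    rmarkdown,
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
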