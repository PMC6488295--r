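Package: clampadapt
Title: Modeling Task-Outcome Effects on Implicit Sensorimotor Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying how task outcome (hitting versus missing a
    target) modulates implicit sensorimotor adaptation under clamped visual
    feedback. Provides the geometry and block structure of error-clamp
    reaching experiments; trial-by-trial simulators for a motor-correction
    state-space model, a population-vector movement-reinforcement model, an
    adaptation-modulation (gain) model, a dual error-signal model, and their
    hybrids; preprocessing of trial-level reach data into baseline-corrected
    cycle series and summary learning metrics; permutation tests and effect
    sizes; multi-start bounded least-squares model fitting with AIC and
    R-squared model comparison; participant-resampling bootstrap confidence
    intervals for parameters; and a synthetic trial-data generator so the
    entire pipeline can be exercised without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
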