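Package: vergedist
Title: Bayesian Estimation of Absolute Distance from Ocular Vergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling how an observer estimates absolute (egocentric)
    distance from the ocular convergence signal. Implements the binocular
    viewing geometry linking vergence angle, fixation distance and retinal
    disparity; a truncated-Gaussian measurement model for vergence noise and
    its exact change-of-variables push-forward to a probability density over
    distance; point estimators under quadratic, absolute and zero-one loss
    (posterior mean, median and peak); trial-level Monte-Carlo simulation of
    response distributions; inference of the vergence noise level implied by
    behavioural distance-estimation data via a quadratic response surface;
    transforms between distance and vergence priors, including the distance
    density consistent with a flat vergence prior and the "internalised"
    prior obtained by passing world distances through the model's
    physical-to-perceived mapping; and a synthetic-data generator emulating
    manual distance-matching experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
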