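Package: melflick
Title: Silent-Substitution Stimulus Design and Flicker-Detection Threshold
    Analysis for Melanopsin Psychophysics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing photoreceptor-directed spectral stimuli by
    silent substitution on a multiprimary light source, simulating
    two-interval forced-choice flicker-detection experiments with interleaved
    adaptive staircases, estimating detection thresholds by maximum-likelihood
    cumulative-Weibull fits, and predicting the perceptual consequences of
    residual stimulus "splatter" (unintended contrast on nominally silenced
    photoreceptor classes). Includes a synthetic multiprimary device model and
    simulated Weibull observers so the full pipeline can be exercised
    end-to-end without hardware.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
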