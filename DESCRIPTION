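Package: hspcfeed
Title: Feedback-Controlled Fed-Batch Expansion of Hematopoietic Stem and
    Progenitor Cells
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An empirical dynamic model of umbilical-cord-blood hematopoietic
    cell culture in which secreted TGF-beta1 accumulates and inhibits stem and
    progenitor cell growth. The package provides the concentration-dependent
    growth / expression-weighted secretion model core, a calibration pipeline
    that turns time-course culture tables into growth-rate and secretion-rate
    correlations, an event-driven fed-batch simulator (media exchange, linear,
    exponential, logarithmic, threshold and PID feeding), a discrete PID
    controller with a filtered derivative term and volume-saturation latch,
    bioprocess design evaluation (volumetric efficiency, differentiation
    constraints, set-point / sampling / fold-volume sweeps), and a synthetic
    data generator for replicate initial populations and training time
    courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
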