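Package: mousefall
Title: Simulation and Analysis of a Gamified Web-Based Mouse-Tracking Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a web-based "catch the falling object" mouse-tracking
    paradigm for spoken-word recognition. Provides a frame-based generative
    simulator of the trial dynamics (falling objects with stochastic
    horizontal wiggle, fall-speed adaptation to the target-word onset,
    tractor-beam clicks and catch adjudication), synthetic participants with
    latent commitment times, session assembly with counterbalanced trial
    orders, and the complete analysis pipeline: regridding of
    variable-frame-rate cursor logs onto a fixed 60 Hz grid, decision-time
    extraction from categorized trajectory state strings, participant- and
    trial-level screening, crossed random-effects models of decision times,
    within-participant (Morey) confidence intervals, and a cluster-bootstrap
    time-course difference analysis. The simulator's ground truth supports
    parameter-recovery studies of the paradigm's measurement properties
    without collecting data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
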