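Package: ethosleep
Title: Sleep Scoring, Closed-Loop Deprivation Simulation and Behavioral
    Fingerprinting for Fly Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying sleep and behavior in Drosophila from
    epoch-level positional tracking data: immobility thresholding and the
    five-minute sleep rule with stimulus masking, a three-state
    (quiescence/micromovement/walking) minute-level ethogram, virtual
    activity-monitor re-scoring, position normalization, homeostatic
    rebound estimation against a control-calibrated expectation,
    Bhattacharyya-distance UPGMA behavioral fingerprinting, circadian
    seasonal decomposition of stimulus time series, Kaplan-Meier lifespan
    analysis with censoring-aware median confidence intervals, and a
    sleep-by-sex lifespan regression. A closed-loop synthetic tracking
    simulator (semi-Markov alternating-bout model with an
    immobility-triggered tube-rotation monitor) generates data with the
    statistical structure the analyses assume, so every stage is testable
    without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    boot,
    optparse,
    withr
Config/testthat/edition: 3
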