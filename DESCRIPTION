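Package: organoidrig
Title: Closed-Loop Organoid Maintenance: Fluid-Volume Vision, Feedback
    Control, and Feed-Effect Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Desk-scale, hardware-free re-implementation of a feedback-driven
    organoid maintenance platform. Estimates conditioned-media volume in
    15 mL conical collection reservoirs from backlit photographs using HSV
    row-profile meniscus detection and a calibrated piecewise cubic
    pixel-area-to-microlitre regression with leave-one-out validation;
    interprets estimates against an expectation ledger and emits corrective
    pump jobs (aspirate, pull, dispense) with escalation, anomaly and
    tube-change rules; provides an in-process publish/subscribe broker with
    MQTT topic semantics, device scheduling with pause/defer, experiment
    metadata and a checksum-verified upload queue; simulates the full rig
    (chamber/reservoir fluid physics, clog faults, reservoir-image renderer
    with ground truth) for closed-loop end-to-end runs; and implements the
    feed-effect spike-train statistic (90-s sliding-window firing rates,
    contrast normalization, no-feed baseline z-scoring) together with a
    synthetic Poisson raster generator and HD-MEA electrode-grid alignment
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
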