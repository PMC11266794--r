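Package: larvadev
Title: Quantifying C. elegans Larval Developmental Timing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying developmental timing in C. elegans larvae:
    extraction of a cell-division density curve from a post-embryonic lineage
    diagram image (row scanning, narrow-element deletion, contiguous-bar
    counting, two-anchor time calibration, inverse-kernel smoothing);
    population activity profiles on a percent-of-stage-completion axis;
    lethargus and feeding metrics from binary pharyngeal-pumping rasters
    sampled at fixed intervals; body-volume morphometrics with isomorphy and
    divergence-onset analyses; and seeded simulators that generate
    ground-truthed versions of every input so the full pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
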