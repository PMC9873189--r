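Package: ferrodecay
Title: Targeted Transcript Normalization and mRNA Decay Modelling for
    Iron-Resupply Time Courses
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing targeted (NanoString-style) transcript count
    panels from iron-limitation/iron-resupply experiments in phytoplankton.
    Implements the four-stage count normalization used for hybridization-based
    panels (positive-control geometric-mean scaling, reference-lane probe
    calibration, probe-attenuation correction and housekeeping normalization,
    with a per-timepoint housekeeping scheme for transcription-inhibited
    samples), broken-line (changepoint) decay modelling of log-scale transcript
    trajectories, half-life estimation from actinomycin-D shut-off series,
    likelihood-ratio tests of decay-rate equality between treatments, and
    supporting fold-change, correlation and ordination summaries. A seeded
    simulator reproduces the experimental design (treatments, sampling grids,
    spike-in ladders, attenuation) so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
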