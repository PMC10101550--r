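Package: chamberchoice
Title: Video Tracking and Scoring for Two-Chamber Forced-Choice Avoidance Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-chamber forced-choice avoidance assays
    in rodents. Tracks a single dark animal on a light background by
    frame differencing (paired reference/comparison frames, binarization,
    morphological opening, centroid extraction), classifies each detection
    into the left or right chamber of a user-defined arena, computes
    centered behavior scores (irritant-chamber occupancy fraction minus
    0.5), aggregates repeated-exposure sessions, and compares groups with
    one- or two-way ANOVA plus Tukey post hoc tests. Includes a seeded
    synthetic-assay simulator (two-state chamber-occupancy Markov model,
    bounded random-walk paths, and a video renderer with ground truth) so
    the whole pipeline can be exercised and validated without recordings.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    car,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
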