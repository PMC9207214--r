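Package: olcquant
Title: Quantification of Oligodendrocyte Lineage Cell Dynamics, Calcium
    Activity, and Sensory Behavior from In Vivo Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantification procedures for intravital imaging studies of
    oligodendrocyte lineage cells (OLCs) in the larval zebrafish spinal cord.
    Provides migration-track featurization (path length, direction changes,
    net displacement, velocity) with k-means clustering and elbow-method
    selection of the cluster count; region-of-interest integrated-density
    measurement from grayscale image stacks with background normalization;
    a Z-score-threshold calcium transient event caller for GCaMP
    integrated-density traces, with per-animal activity summaries, stimulus
    epoch comparisons and activity heatmaps; sheath morphometry group
    comparisons and per-fish across-day stability tests; scoring of the
    cold-induced shiver response and tactile response proportions; timing
    statistics for contact with the dorsal root entry zone; and seeded
    synthetic-data generators with ground truth so every stage can be
    exercised and validated without raw microscopy movies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mclust,
    signal,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
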