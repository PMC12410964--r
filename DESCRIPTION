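Package: flyVAM
Title: Video Activity Monitoring Analytics for Single-Fly Chamber Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing and analysis of pose-tracking tables from video
    recordings of single Drosophila in rectangular chambers. Reads the
    single-animal DeepLabCut CSV dialect, cleans rare out-of-chamber
    misdetections by flank-averaged interpolation, and computes circadian
    locomotor metrics: binned frame-to-frame distance, virtual
    infrared-beam (midline) crossing counts, sleep bouts under the
    five-minute inactivity rule, average-day profiles, and day/night group
    comparisons. Positional analyses include per-second position traces,
    occupancy heatmaps and longitudinal food-preference histograms with
    between-group tests. A ground-truthed two-state random-walk simulator
    generates synthetic recordings with circadian rate modulation,
    light-transition startle peaks, midday siesta, food attraction and
    injected misdetections, so the whole pipeline is testable without
    hardware or video.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2,
    rlang,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
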