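Package: meahypoxia
Title: Network Activity and Cell Viability Analysis for In Vitro Hypoxia Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for micro-electrode array (MEA) recordings of
    neuronal cultures exposed to hypoxia, together with a fluorescence-image
    based live/apoptotic/dead cell quantification. Implements threshold-based
    spike detection on band-passed extracellular traces, max-interval
    single-channel burst detection, network-burst detection by temporal
    overlap chaining, per-well firing and bursting metrics, stimulation-window
    masking, normalization of metric time-courses to a normoxia baseline with
    condition-level aggregation and statistics, and Otsu-threshold nucleus
    counting with reporter-channel classification. A synthetic-data module
    generates seeded spike trains, voltage traces and three-channel
    micrographs with ground truth so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
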