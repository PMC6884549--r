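Package: bertx
Title: Quantification of Transcription-Associated Base Excision Repair Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy analysis of the quantitative assays used to study
    alkyladenine-DNA-glycosylase (AAG) initiated base excision repair in
    transcribed chromatin: fluorescence-based host-cell reactivation (FM-HCR)
    repair-capacity scoring from flow-cytometry event tables, qPCR-based
    region-specific lesion mapping under a Poisson digestion model, ChIP-qPCR
    percent-input and promoter-relative occupancy, delta-delta-Ct expression,
    two-knockout differential-expression overlap and direction-quadrant
    classification, and comet-FLARE percent-tail summaries. Ships seeded
    synthetic-data generators with recorded ground truth for every assay so
    each estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    multcomp,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
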