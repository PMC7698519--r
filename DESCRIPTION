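Package: kinomeRank
Title: Upstream Kinase Inference and Rank Aggregation for Peptide Kinome Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-exposure peptide kinome-array
    fluorescence data: per-peptide exposure-slope quantification with linearity
    and detectability filtering, replicate-averaged fold-change calling,
    kinase-peptide substrate mapping with database-style selection rules,
    resampling-based upstream kinase family scoring (random-sampling null with
    Z-scores and directionality), and inclusive-percentile rank aggregation of
    heterogeneous kinase-scoring pipelines into unweighted and weighted
    consensus rankings. Includes a synthetic-data generator with spiked
    differentially active kinases so every stage is testable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
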