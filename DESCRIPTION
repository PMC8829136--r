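Package: woundchron
Title: Chronology of the Wounding Transcriptional Response in Tea Leaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Time-series analysis of the mechanical-wounding (turnover)
    response of oolong-tea leaves: per-time-point negative-binomial
    differential expression with first-differential-expression (FDEG)
    timing, fuzzy c-means clustering of fold-change trajectories,
    hypergeometric overrepresentation of transcription-factor families,
    functional terms and promoter motifs, inference of contiguous
    transcriptional phases from time-point correlation structure, and a
    compact weighted co-expression network with module-volatile
    integration. Includes a synthetic-data generator with known ground
    truth so that every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
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
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
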