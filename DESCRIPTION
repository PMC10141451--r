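Package: mirtrack
Title: Consensus miRNA Binding-Site Prediction and UCSC Track Generation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts microRNA binding sites over full-length mature
    transcripts with three predictor engines (a seed-match classifier, a
    complementarity alignment/energy scorer, and a site-accessibility
    scorer), retains only high-confidence sites called by all three engines
    with a minimum transcript-space overlap, projects the retained sites
    splice-aware onto genome coordinates, and serializes them as UCSC
    bedDetail custom tracks, per-site detail pages and a flat CSV. Includes
    adapters for native TargetScan/miRanda/PITA output files and a seeded
    synthetic-fixture generator with planted ground-truth sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    withr,
    ggplot2,
    generics,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
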