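Package: towardsig
Title: Shared Somatic Hypermutation Detection and Towards Analysis for
    IGHV Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining somatic hypermutation (SHM) patterns in
    immunoglobulin heavy-chain variable (IGHV) gene rearrangements.
    Detects mutations shared with other germline IGHV genes (SH
    mutations), builds per-mutation and per-germline feature tables
    (SHPD, nonSHPD, GSHD), and aggregates per-sequence scored
    towards-lists with a Borda-inspired voting scheme into consensus
    rankings of "towards" genes, with clan, gene, and functionality
    movement summaries and subset clustering. Includes a seeded
    synthetic-data generator producing toy germline references and
    mutated patient cohorts with known ground truth, so the whole
    pipeline can be exercised without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
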