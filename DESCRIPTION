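Package: graftgsa
Title: Gene-Set Discovery of Redundant Allograft Rejection Pathways and
    Drug Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maxmean gene-set analysis with restandardization and a
    label-permutation false discovery rate, in two-class and ordinal
    ("quantitative") modes, for discovering immune pathways enriched in
    allograft rejection transcriptomes; cross-dataset replication;
    rule-based curation of activated-immune-cell gene-sets from
    differential-expression tables; drug-repositioning filters over open
    compound-gene interaction tables; delta-delta-Ct relative
    quantification for qPCR validation; and seed-deterministic synthetic
    data generators with known ground truth so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
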