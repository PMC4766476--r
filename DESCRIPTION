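Package: redoxscreen
Title: Hit Calling for Dual-Luciferase RNAi Screens and Pattern-Based
    Stress-Transcriptome Gene Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing cell-based dual-luciferase RNAi screens
    and four-condition oxidative-stress RNA-seq experiments. Implements
    robust Z-score normalization of firefly/renilla reporter ratios with a
    multi-dsRNA consensus rule for calling pathway inducers and
    suppressors; library-size normalization, Welch tests and
    Benjamini-Hochberg correction for condition-pair differential
    expression; expression-profile clustering under one-minus-Pearson
    distance with pattern-template labelling and multi-criteria gene-group
    selection (including a geometric-mean dependence rule); hypergeometric
    term enrichment with Bonferroni or BH correction; and seeded
    synthetic-data generators with planted ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    utils,
    withr
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
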