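Package: tilmonitor
Title: Immune Monitoring Analytics for Neoadjuvant Immunotherapy Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for trial-style immune monitoring of
    tumor-infiltrating lymphocytes (TIL). Computes TCR-beta repertoire
    clonality, Morisita-Horn overlap, top-clone tracking and reactive-clone
    calls on sorted-subset repertoires; a three-component CD8 TIL activation
    index with responder classification from flow-cytometry subset panels;
    a somatic-variant to neoepitope candidate chain (filter criteria, 25-mer
    windowing, mutation-spanning 8-11mer enumeration, transcript-level
    prioritization, pluggable binding scorer); multiplex-IHC region-of-interest
    aggregation, tumor-vs-stroma fold changes and flow-IHC concordance;
    ELISpot positivity calls; and Kaplan-Meier, log-rank and reverse-KM
    follow-up endpoints. A seeded synthetic cohort generator emulates the
    statistical structure of such trials (power-law clone abundance, planted
    cross-subset sharing, responder effect sizes, group-dependent survival)
    so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stringr,
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
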