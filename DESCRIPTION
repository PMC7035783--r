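Package: lincfinder
Title: Identification and Characterization of Long Intergenic Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for discovering long intergenic
    non-coding RNAs (lincRNAs) from assembled transcriptomes. Assembled
    transcripts are classified against a reference annotation with
    Cuffcompare-style class codes, filtered to multi-exon intergenic
    candidates, and screened for coding potential with an alignment-free
    logistic model over ORF length and coverage, the Fickett TESTCODE
    statistic, and hexamer usage bias, together with optional
    conservation-score and protein-domain decision rules and a maximal-ORF
    filter. Retained lincRNAs are characterized by an entropy-based
    Jensen-Shannon tissue-specificity score, compared to external lncRNA
    catalogues by locus overlap, and linked to candidate cis-regulated
    neighboring protein-coding genes via expression correlation and
    hypergeometric GO-term enrichment. A seeded synthetic-data generator
    emulates every input with ground-truth labels for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
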