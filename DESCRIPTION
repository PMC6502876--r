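Package: primerbias
Title: Primer Coverage Bias Evaluation for Nitrogen-Cycle Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico PCR evaluation of degenerate 16S rRNA gene primers for
    partial nitritation anammox (PNA) microbial communities. Computes per-taxon
    primer coverage against a reference sequence collection, propagates coverage
    into theoretical absolute and relative quantification bias, measures
    percentage dissimilarity between primer pairs (Bray-Curtis), assesses primer
    usage across published studies, and encodes a decision-tree framework for
    planning PCR-based studies. A synthetic reference generator with planted
    primer-site intactness provides ground truth for every analysis at desk
    scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    Biostrings,
    withr
Config/testthat/edition: 3
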