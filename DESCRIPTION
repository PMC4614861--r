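Package: domevol
Title: Domain-Resolved Molecular Evolution of Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for comparative molecular-evolution
    analysis of a protein family, worked end-to-end on the cold-sensitive
    TRPM8 cation channel. Provides domain-resolved conservation profiling
    over a reference-anchored region map, Dickerson-style rate-versus-
    divergence-time curves with conserved-protein baselines, mutual-
    information coevolution networks with permutation null z-scores,
    missense-variant triage combining Grantham deviation with SIFT and
    PolyPhen calls, gene-neighborhood (synteny) conservation via signed
    longest-common-subsequence block scores, distance-based phylogenetics,
    and a closed-loop sequence/variant/gene-order simulator so every stage
    is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    Matrix,
    withr,
    Biostrings,
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
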