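Package: herbauth
Title: ITS2 Metabarcoding Quality Control for Multi-Ingredient Herbal
    Preparations
Version: 1.0.0
Authors@R:
    person("herbauth", "developers", email = "herbauth@example.org",
           role = c("aut", "cre"))
Description: Implements a quality-control pipeline for authenticating the
    biological composition of multi-ingredient herbal preparations from
    high-throughput ITS2 amplicon sequencing: phred/length read filtering,
    PCR-primer masking, profile-HMM annotation and trimming of the conserved
    5.8S/28S rRNA flanks (which otherwise cause cross-species false-positive
    matches), curation of a species-labelled ITS2 reference database,
    identity-threshold best-hit species assignment with abundance tabulation
    and prescription screening. Companion tools cover in-silico qPCR primer
    specificity (mismatch plus 3'-terminal rules), Ct presence calls, and
    digital-PCR Poisson quantification. A deterministic amplicon simulator
    with Ion-Torrent-like homopolymer errors provides ground-truth data so
    the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
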