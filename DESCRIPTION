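Package: oxogrepair
Title: Phyletic Profiling and Loss Mapping of 8-oxo-G Repair Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls presence or absence of the 8-oxoguanine (8-oxo-G) base
    excision repair families MutY, MutM and MutT across proteomes using
    reciprocal-best-hit homology search with exact affine-gap local alignment,
    empirically calibrated E-values, position-specific scoring matrix (PSSM)
    domain validation with specific-versus-similar rejection against Nth-like
    decoys, and extension of truncated gene predictions from genomic sequence.
    Maps gene losses onto a species tree by Dollo parsimony and detects
    clade-specific sequence insertions near catalytic motifs in protein
    multiple alignments. Ships a sequence-evolution simulator that plants
    losses, decoy paralogues, truncations and insertions along a tree and
    emits truth tables, so every stage of the pipeline has a recovery target.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
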