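Package: pepmhc
Title: Interface Analytics for Designed Peptide-MHC-I Binders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytics for structure-based design funnels that select
    peptide-MHC class I (pMHC-I) binders which engage the presented peptide
    rather than the MHC scaffold. Parses and validates binder/pMHC-I
    complexes, classifies peptide positions as groove anchors or
    outward-facing, computes contact maps, hydrogen bonds, Shrake-Rupley
    solvent accessibility and per-design engagement metrics, scores on- versus
    off-target peptide specificity with a pluggable scorer contract and a
    deterministic contact-potential proxy, scans proteomes for potential
    cross-reactive peptides with HLA anchor-motif filtering and
    outward-position-weighted similarity, and provides Kabsch superposition,
    model-versus-crystal comparison, CD69 activation summaries and sort
    enrichment analysis. Ships deterministic generators of toy pMHC-I-like
    structures and synthetic proteomes so every analysis is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
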