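# pepmhc

Analytics for structure-based design of **peptide–MHC class I (pMHC-I)
binders** — proteins (e.g. CAR recognition domains) that must distinguish
one disease-associated peptide from the thousands of self peptides
presented on the same HLA allele. Specific recognition requires reading
the peptide's **outward-facing residues** while avoiding extensive contact
with the ubiquitously shared MHC surface. `pepmhc` implements the
computational funnel around that idea:

1. **Structure model** — parse/validate binder/pMHC-I complexes (PDB or
   mmCIF), classify peptide positions as groove `ANCHOR` vs `OUTWARD` from
   side-chain MHC contact fraction and relative side-chain SASA.
2. **Engagement metrics** — heavy-atom contact maps, hydrogen bonds
   (heavy-atom proxy criteria: d ≤ 3.5 Å, donor angle ≥ 120°),
   Shrake–Rupley SASA on a deterministic lattice, per-design metrics
   (peptide vs MHC contact counts, peptide contact fraction, outward
   coverage) and threshold triage.
3. **Specificity** — the scoring contract `margin = s_on − aggregate(s_off)`
   with worst-case or mean aggregation and strict-greater target ranks,
   fed either by a deterministic contact-potential proxy scorer or by real
   predictor scores from TSV tables.
4. **Cross-reactivity scan** — sliding-window proteome enumeration, HLA
   anchor-motif filtering, and outward-position-weighted substitution
   similarity (`sum_i w_i * M[q_i, c_i]`, default BLOSUM62 with w = 1 at
   outward positions, 0 at anchors).
5. **Validation** — Kabsch superposition (SVD, reflections excluded),
   model-vs-crystal comparison (binder-Cα RMSD; interface all-atom RMSD
   over model-defined interface residues), CD69 activation summaries and
   NGS sort enrichment (`log2((f_post+p)/(f_pre+p))`).
6. **Synthetic fixtures** — deterministic toy pMHC-I geometries and
   planted-truth proteomes so every computation is testable offline.

Everything is tidyverse-shaped: data frames in, tibbles out, `plot_*()`
functions for each result type, `tidy()`/`glance()` for superposition fits.

## Worked example

```r
library(pepmhc)

# a toy complex: MAGE-A3 peptide, anchors P3/P9, binder reading P5/P7/P8
cx  <- make_toy_pmhc(toy_spec(peptide = "EVDPIGHLY",
                              anchor_positions = c(3, 9),
                              binder_contact_positions = c(5, 7, 8)))
cls <- classify_peptide_positions(cx)
dplyr::count(cls, class)
#>   class        n
#> 1 ANCHOR       3     # P3, P9, and the glycine at P6 (no readable side chain)
#> 2 OUTWARD      6

met <- engagement_metrics(cx, cls, design_id = "toy")
met[, c("n_peptide_contacts", "n_mhc_contacts", "peptide_contact_fraction")]
#>   n_peptide_contacts n_mhc_contacts peptide_contact_fraction
#> 1                  3              0                        1
```

The binder touches only the peptide (contact fraction 1 — the design goal)
at exactly the three designated positions. Specificity against the
Titin-derived off-target peptide, with the proxy scorer:

```r
peptide_identity_margin(cx, "EVDPIGHLY", c(titin = "ESDPIVAQY"))
#> margin 1.156, target_rank 1   (positive: on-target preferred)
```

Scan a synthetic proteome for confusable peptides — the planted exact
match returns at rank 1, and the two most confusable near-matches share
the outward-facing residues:

```r
prot <- make_synthetic_proteome(100, 500, seed = 1,
          planted = tibble::tibble(sequence = "EVDPIGHLY",
                                   protein_index = 10, offset = 100))
scan_proteome(prot, "EVDPIGHLY", motif = motif_table("A*01:01"), top_n = 3)
#>   rank  protein_id start  sequence anchors_pass similarity
#> 1    1 protein_010   100 EVDPIGHLY         TRUE         38
#> 2    2 protein_088   288 QIEAILHDY         TRUE          8
#> 3    3 protein_075   187 EIDCAQHHY         TRUE          7
```

A command-line interface wraps the same functions
(`exec/pepmhc <subcommand>`; subcommands `fixtures`, `triage`,
`specificity`, `scan`, `compare`, `activation`), always writing a
`manifest.json` with the resolved configuration and seed.

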