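---
title: "Analytics for designed peptide-MHC-I binders: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytics for designed peptide-MHC-I binders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmhc)
library(tibble)
```

## The problem

Class I MHC molecules display 8–11-residue peptides from intracellular
proteins in a groove formed by two long helices. A therapeutic binder (for
example the recognition domain of a chimeric antigen receptor) must
distinguish one disease-associated peptide from the thousands of self
peptides presented on the same HLA allele. Structurally, the peptide offers
only a small readable surface: its anchor side chains (commonly position 2
and the C-terminal position) are buried in the groove and are invisible to
a binder, while its outward-facing side chains point into solvent and are
the only peptide-specific signal available. A specific binder must
therefore read the outward-facing residues while touching the
ubiquitously shared MHC surface as little as possible.

`pepmhc` implements the analytics such a design campaign runs after the
generative steps: classify the peptide's positions, quantify how much of a
candidate's interface engages the peptide rather than the MHC, score
on-target vs off-target peptide preference, scan a proteome for potentially
cross-reactive peptides, and compare design models to experimental
structures or functional readouts. Generative backbone sampling, neural
sequence design, and structure prediction are deliberately out of scope:
the package defines the scoring *contracts* those tools feed into, plus a
deterministic proxy scorer so everything can be exercised at desk scale.

## Position classification

`classify_peptide_positions()` labels each peptide position from two
geometric quantities, computed with the binder excluded:

* **side-chain MHC contact fraction** — the fraction of side-chain heavy
  atoms within a contact cutoff (default 4.5 Å, the common heavy-atom
  interface convention) of any MHC heavy-chain heavy atom. Glycine has no
  side chain and is assigned fraction 1 by convention: it cannot present an
  outward-facing side chain, so it should never be treated as readable.
* **relative side-chain SASA** — side-chain solvent accessibility in the
  binder-less complex divided by the same residue's side-chain SASA in
  isolation. This normalisation makes the quantity comparable across
  residue sizes without a lookup table of reference areas.

A position is `ANCHOR` when the contact fraction is at least 0.5, `OUTWARD`
when the fraction is at most 0.2 *and* the relative SASA is at least 0.2,
and `INTERMEDIATE` otherwise. There is no community-standard operational
definition of "outward-facing"; these thresholds separate groove-buried
from solvent-exposed side chains cleanly on idealized geometry and are all
exposed as arguments, so a campaign can tighten them against its own
structures.

## Engagement metrics and triage

`engagement_metrics()` summarises a candidate design: binder–peptide and
binder–MHC heavy-atom contact counts (cutoff 4.5 Å), the fraction of all
binder contacts that involve the peptide, hydrogen bonds across the
binder–peptide interface, and *outward coverage* — the fraction of OUTWARD
positions receiving at least one binder contact. When the binder makes no
contacts at all the contact fraction is reported as `NA`, never 0/0.

Hydrogen bonds use heavy-atom proxies only (donor–acceptor distance ≤ 3.5
Å, antecedent–donor–acceptor angle ≥ 120°), because design models and
crystal structures place hydrogens differently or not at all. Donor and
acceptor capability comes from a packaged per-residue table; when a
reduced-detail model lacks a donor's canonical antecedent atom the angle
falls back to CB, then CA. Pairs within a residue, and backbone pairs of
covalently adjacent residues, are excluded as covalent-geometry artifacts.

`triage_designs()` applies minima to these metrics. The defaults
(≥ 10 peptide contacts, peptide contact fraction ≥ 0.25, outward coverage
≥ 0.5, ≥ 1 hydrogen bond) are documented heuristics for "extensive peptide
engagement with limited MHC contact" — reasonable for full-atom design
models, deliberately conservative, and meant to be tuned per campaign. An
`NA` metric fails its criterion rather than passing silently.

## Specificity scoring

All scorers obey one orientation: **higher = more favorable**; energy-like
scorers must negate before reporting. `specificity_margin()` reduces an
on-target score and a set of off-target scores to

* `margin = on_score − aggregate(off_scores)`, with the worst-case maximum
  as the default aggregate (the margin against the most dangerous
  off-target) and the mean as the alternative, since reasonable campaigns
  differ on this; and
* `target_rank = 1 + #{off-targets strictly above the target}`, so ties
  share the better rank.

The packaged proxy scorer, `proxy_peptide_score()`, threads a candidate
sequence onto the fixed peptide backbone and sums a residue-contact
potential over Cβ–Cβ pairs (Cα for glycine) within 8 Å — the usual
coarse-grained contact convention. The default potential is a transparent
symmetric 20×20 matrix built from products of rescaled Kyte–Doolittle
hydropathies, so hydrophobic–hydrophobic contacts are most favorable. It
is a deterministic test harness with the qualitative structure of
knowledge-based contact potentials, **not** a reimplementation of neural
confidence scores; real predictor outputs enter through TSV score tables
(`read_score_table()`, `specificity_from_table()`) and flow through
identical margin/rank logic. The margin threshold for "specific enough"
defaults to 0 (strict on-target superiority) with no hidden default beyond
that.

## Proteome cross-reactivity scan

`scan_proteome()` composes three stages, each exposed separately:
enumerate every length-k window with provenance; keep windows satisfying
the allele's anchor motif (a presence/absence filter standing in for
presentability — peptides that cannot anchor are never displayed); and
score the survivors against the query with a position-weighted substitution
similarity. The default weights are 1 at outward-facing positions and 0 at
anchors — the binder can only read the outward face, so two peptides
sharing their outward residues are maximally confusable regardless of
anchor identity. The default matrix is BLOSUM62; an identity matrix turns
the score into a weighted identity count. Packaged anchor motifs for
A\*01:01, A\*02:01, A\*03:01 and C\*07:02 encode textbook primary anchors
and are editable defaults, not measured binding motifs; the package
deliberately does not predict binding affinity. Ties in similarity are
broken by protein id and offset so output is reproducible.

## Structural and functional validation

`kabsch_superpose()` implements the SVD form of least-squares rigid
superposition with reflections excluded; collinear point sets are flagged
as degenerate rather than silently returning one of the many optima.
`compare_model_to_crystal()` reports backbone accuracy (binder-Cα RMSD
after superposing on those same Cα — the frame choice is explicit and an
MHC-frame alternative is provided, since a published RMSD rarely states
its frame) and interface accuracy (all-heavy-atom RMSD over model-defined
interface residues). The interface set is defined on the *model* at a
configurable cutoff, and the companion CLI report prints interface-residue
counts at 3.5–5.0 Å, because published interface-residue counts rarely
state their cutoff either.

`activation_summary()` and `sort_enrichment()` cover the functional
readouts: CD69 MFI fold-changes over a control condition (sample SD,
defined as 0 for single replicates), and log2 enrichment of pre/post sort
sequencing counts on the frequency scale with a pseudocount
(`log2((f_post + p)/(f_pre + p))`). The default pseudocount is
Jeffreys-style, 0.5 divided by the mean pool total; passing an explicit
`p` makes the statistic exactly invariant to sequencing depth.

## Synthetic fixtures: what they do and do not show

`make_toy_pmhc()` builds an idealized complex: an extended peptide (3.5
Å/residue) flanked by two antiparallel ideal helices (1.5 Å rise, 100°
twist per residue — textbook values), anchor side chains pointing into the
groove, the rest pointing to solvent, and a binder helix above the peptide
with one serine "reader" per designated contact position placed so that
its OG contacts (and, for polar side chains, hydrogen-bonds) exactly that
position's side-chain tip. Side chains are reduced to Cβ plus one
pseudo-atom along the normal, which is sufficient for every contact, SASA
and threading computation in the package. All generators are pure
functions of their spec and seed.

These fixtures make the *designed truth* checkable by brute force: which
positions are anchors, which positions the binder touches, how many
hydrogen bonds exist. They do not reproduce real pMHC-I geometry — no
groove floor β-sheet, no rotamers, no packing — so green tests certify the
correctness of the computations, not the biological realism of thresholds.
Threshold defaults should still be reviewed against real structures before
a campaign relies on them.

`make_synthetic_proteome()` samples uniform residue frequencies by default
(a background-frequency alternative is exposed) and overwrites planted
substrings at stated loci, giving scan tests an exact planted truth.

## Numerical choices

* SASA uses a deterministic Fibonacci lattice (default 240 points per
  atom; 960 in accuracy checks). The lattice is fixed in the lab frame, so
  SASA is rotation-invariant only up to discretization (a few percent);
  contact-based quantities are exactly invariant. Radii default to C 1.70,
  N 1.55, O 1.52, S 1.80 Å and are replaceable.
* Alternate locations resolve to the highest-occupancy conformer, ties to
  file order; hydrogens are ignored everywhere; known modified residues
  (MSE, SEP, TPO, ...) map to their parents, and chains with unmappable
  residues are rejected loudly rather than silently dropped.
* Kabsch: the reflection case is handled by sign-flipping the smallest
  singular direction; RMSD ties in ranking functions break
  lexicographically so all orderings are deterministic.
* Problem sizes in the test suite (20 oracle fixtures, 1000 random score
  tables, a 100 × 500-residue proteome, 10 perturbation seeds) were chosen
  so the whole suite completes in about two minutes while still exercising
  every code path against an independent oracle.

## Known limitations

Geometry only — no physics-based energies, no protonation, no relaxation.
Anchor motifs are presence/absence filters, not affinity predictions. The
proxy scorer's absolute values are meaningless; only its deterministic
structure is load-bearing, and any conclusions about real designs must
come from real predictor scores supplied as tables. The toy fixtures'
idealized groove means SASA-threshold behavior on real structures should
be validated separately.
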