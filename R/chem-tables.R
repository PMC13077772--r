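# Static chemistry tables shared across modules: residue codes, van der
# Waals radii, hydrogen-bond donor/acceptor atoms, hydropathy values and the
# default coarse-grained contact potential.

# canonical 20 residues, three-letter -> one-letter
.aa3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
.aa1 <- stats::setNames(names(.aa3), unname(.aa3))

# common modified residues mapped to their parent standard residue;
# anything else nonstandard causes the chain to be rejected at load time
.aa_modified <- c(
  MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR", CSO = "CYS",
  HYP = "PRO", MLY = "LYS", M3L = "LYS", PCA = "GLU", KCX = "LYS",
  CME = "CYS", CSD = "CYS", OCS = "CYS", FME = "MET", HIC = "HIS"
)

.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

#' Default van der Waals radii (\enc{Å}{Angstrom}) used by the
#' Shrake–Rupley solvent-accessibility calculation
#'
#' A named vector of per-element radii. Only heavy atoms are ever assigned a
#' radius; hydrogens are ignored throughout the package.
#'
#' @return Named numeric vector of radii in \enc{Å}{Angstrom}.
#' @export
#' @examples
#' default_vdw_radii()
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)
}

# Kyte-Doolittle hydropathy, one-letter keys
.kd_hydropathy <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

#' Default residue-contact potential for the proxy peptide scorer
#'
#' A symmetric 20 x 20 matrix of contact pseudo-energies (arbitrary units,
#' negative = favorable) indexed by one-letter amino-acid codes. Values are
#' derived from the product of rescaled Kyte–Doolittle hydropathies, so
#' hydrophobic–hydrophobic contacts are the most favorable — the qualitative
#' structure of knowledge-based residue contact potentials. This is a
#' deterministic test-harness scorer for exercising specificity logic, not a
#' substitute for learned structure/sequence models; any user-supplied
#' symmetric matrix with the same indexing can be used instead.
#'
#' @return 20 x 20 symmetric numeric matrix with dimnames the one-letter
#'   amino-acid codes.
#' @export
#' @examples
#' p <- contact_potential()
#' p["L", "L"] < p["K", "E"]  # hydrophobic pair more favorable
contact_potential <- function() {
  h <- (.kd_hydropathy + 4.5) / 9  # rescale to [0, 1]
  aa <- names(.kd_hydropathy)
  m <- -(0.5 + 5.5 * outer(h, h))
  dimnames(m) <- list(aa, aa)
  m[aa[order(aa)], aa[order(aa)]]
}

# Hydrogen-bond chemistry (heavy-atom proxies, no explicit hydrogens).
# Backbone N is a donor for every residue except proline; backbone O (and
# OXT) accepts for every residue. Side-chain capability per residue below.
# "antecedent" is the heavy atom bonded to the donor, used for the
# donor-geometry angle; when a reduced-detail model lacks the canonical
# antecedent, detect_hbonds() falls back to CB then CA.
.hbond_sidechain_donors <- tibble::tribble(
  ~residue_name, ~atom_name, ~antecedent,
  "ARG", "NE",  "CD",
  "ARG", "NH1", "CZ",
  "ARG", "NH2", "CZ",
  "ASN", "ND2", "CG",
  "GLN", "NE2", "CD",
  "HIS", "ND1", "CG",
  "HIS", "NE2", "CD2",
  "LYS", "NZ",  "CE",
  "SER", "OG",  "CB",
  "THR", "OG1", "CB",
  "TRP", "NE1", "CD1",
  "TYR", "OH",  "CZ"
)

.hbond_sidechain_acceptors <- tibble::tribble(
  ~residue_name, ~atom_name,
  "ASN", "OD1",
  "ASP", "OD1",
  "ASP", "OD2",
  "GLN", "OE1",
  "GLU", "OE1",
  "GLU", "OE2",
  "HIS", "ND1",
  "HIS", "NE2",
  "SER", "OG",
  "THR", "OG1",
  "TYR", "OH"
)

# side-chain "tip" atom used by the reduced-detail fixture representation
# (CB plus one pseudo-atom along the inward/outward normal)
.sidechain_tip <- c(
  ARG = "NH1", ASN = "ND2", ASP = "OD1", CYS = "SG", GLN = "NE2",
  GLU = "OE1", HIS = "NE2", ILE = "CD1", LEU = "CD1", LYS = "NZ",
  MET = "SD", PHE = "CZ", PRO = "CG", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", VAL = "CG1"
)

aa_three_to_one <- function(residue_name) {
  mapped <- ifelse(residue_name %in% names(.aa_modified),
                   unname(.aa_modified[residue_name]), residue_name)
  out <- unname(.aa3[mapped])
  out
}

aa_one_to_three <- function(letter) {
  out <- unname(.aa1[letter])
  if (anyNA(out)) {
    stop("unknown amino-acid letter(s): ",
         paste(unique(letter[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

element_from_atom_name <- function(atom_name) {
  # leading element symbol of a PDB atom name (digits stripped); two-letter
  # symbols only for the few that occur in proteins
  nm <- toupper(gsub("[0-9']", "", atom_name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "BR"),
         two, substr(nm, 1, 1))
}
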