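# Geometric engagement statistics: cross-group contact maps, hydrogen-bond
# detection with heavy-atom donor proxies, per-design engagement metrics and
# threshold-based design triage.

#' Heavy-atom contact pairs between two chain-role groups
#'
#' Enumerates all (and only) heavy-atom pairs across the two groups whose
#' Euclidean distance is at most `cutoff`. The two groups must not share a
#' chain.
#'
#' @param x A [pmhc_complex()].
#' @param group_a,group_b Character vectors of chain roles (e.g. `"BINDER"`,
#'   `c("MHC_HEAVY", "B2M")`).
#' @param cutoff Distance cutoff in \enc{Å}{Angstrom} (default 4.5, the
#'   usual heavy-atom interface convention).
#' @return Tibble with one row per contact: `chain_a`, `residue_a`,
#'   `atom_a`, `chain_b`, `residue_b`, `atom_b`, `distance`. The cutoff and
#'   group selectors are carried in attributes `cutoff`, `group_a`,
#'   `group_b`.
#' @export
contact_pairs <- function(x, group_a, group_b, cutoff = 4.5) {
  stopifnot(cutoff > 0)
  a <- role_atoms(x, group_a)
  b <- role_atoms(x, group_b)
  if (nrow(a) == 0) stop("group_a selects no atoms", call. = FALSE)
  if (nrow(b) == 0) stop("group_b selects no atoms", call. = FALSE)
  shared <- intersect(unique(a$chain_id), unique(b$chain_id))
  if (length(shared) > 0) {
    stop("groups overlap on chain(s): ", paste(shared, collapse = ", "),
         call. = FALSE)
  }
  d2 <- cross_dist2(as.matrix(a[, c("x", "y", "z")]),
                    as.matrix(b[, c("x", "y", "z")]))
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  out <- tibble::tibble(
    chain_a = a$chain_id[hit[, 1]], residue_a = a$residue_index[hit[, 1]],
    atom_a = a$atom_name[hit[, 1]],
    chain_b = b$chain_id[hit[, 2]], residue_b = b$residue_index[hit[, 2]],
    atom_b = b$atom_name[hit[, 2]],
    distance = sqrt(pmax(d2[hit], 0))
  ) |>
    dplyr::arrange(.data$chain_a, .data$residue_a, .data$atom_a,
                   .data$chain_b, .data$residue_b, .data$atom_b)
  attr(out, "cutoff") <- cutoff
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  out
}

# donor atoms (with antecedent fallback CB -> CA) and acceptor atoms of an
# atom subset, using the packaged per-residue capability tables
hbond_donors <- function(atoms) {
  bb <- dplyr::filter(atoms, .data$atom_name == "N",
                      .data$residue_name != "PRO") |>
    dplyr::mutate(antecedent = "CA")
  sc <- dplyr::inner_join(atoms, .hbond_sidechain_donors,
                          by = c("residue_name", "atom_name"))
  dplyr::bind_rows(bb, sc)
}

hbond_acceptors <- function(atoms) {
  bb <- dplyr::filter(atoms, .data$atom_name %in% c("O", "OXT"))
  sc <- dplyr::inner_join(atoms, .hbond_sidechain_acceptors,
                          by = c("residue_name", "atom_name"))
  dplyr::bind_rows(bb, sc)
}

#' Detect hydrogen bonds between two groups using heavy-atom geometry
#'
#' Hydrogen positions differ between design models and crystal structures,
#' so detection uses heavy-atom proxies only: an N/O donor and an N/O
#' acceptor form a bond when their distance is at most `d_max` and the angle
#' antecedent–donor–acceptor is at least `angle_min` (the antecedent is the
#' heavy atom bonded to the donor; when the canonical antecedent is absent —
#' e.g. in reduced-detail models — CB, then CA, of the donor residue is
#' used). Donor/acceptor capability comes from a packaged per-residue table.
#' Pairs within one residue are never reported, nor backbone–backbone pairs
#' of adjacent residues in the same chain (those are covalent-geometry
#' artifacts, not hydrogen bonds).
#'
#' @param x A [pmhc_complex()].
#' @param donor_group,acceptor_group Chain-role selectors; may be equal
#'   (intra-group bonds, e.g. a helix).
#' @param d_max Donor–acceptor distance cutoff in \enc{Å}{Angstrom}.
#' @param angle_min Minimum donor angle in degrees.
#' @return Tibble with one row per bond: donor/acceptor chain, residue,
#'   atom, `distance`, `angle`.
#' @export
detect_hbonds <- function(x, donor_group, acceptor_group,
                          d_max = 3.5, angle_min = 120) {
  don_atoms <- role_atoms(x, donor_group)
  acc_atoms <- role_atoms(x, acceptor_group)
  if (nrow(don_atoms) == 0) stop("donor group selects no atoms", call. = FALSE)
  if (nrow(acc_atoms) == 0) stop("acceptor group selects no atoms", call. = FALSE)

  don <- hbond_donors(don_atoms)
  acc <- hbond_acceptors(acc_atoms)
  empty <- tibble::tibble(
    donor_chain = character(), donor_residue = integer(),
    donor_atom = character(), acceptor_chain = character(),
    acceptor_residue = integer(), acceptor_atom = character(),
    distance = numeric(), angle = numeric()
  )
  if (nrow(don) == 0 || nrow(acc) == 0) return(empty)

  # resolve antecedent coordinates with CB -> CA fallback
  all_atoms <- x$atoms
  ante_xyz <- matrix(NA_real_, nrow(don), 3)
  for (i in seq_len(nrow(don))) {
    res <- all_atoms[all_atoms$chain_id == don$chain_id[i] &
                       all_atoms$residue_index == don$residue_index[i], ]
    for (cand in unique(c(don$antecedent[i], "CB", "CA"))) {
      hitrow <- which(res$atom_name == cand)
      if (length(hitrow) > 0) {
        ante_xyz[i, ] <- as.numeric(res[hitrow[1], c("x", "y", "z")])
        break
      }
    }
  }
  ok <- stats::complete.cases(ante_xyz)
  don <- don[ok, , drop = FALSE]
  ante_xyz <- ante_xyz[ok, , drop = FALSE]
  if (nrow(don) == 0) return(empty)

  dxyz <- as.matrix(don[, c("x", "y", "z")])
  axyz <- as.matrix(acc[, c("x", "y", "z")])
  d2 <- cross_dist2(dxyz, axyz)
  hit <- which(d2 <= d_max^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)

  di <- hit[, 1]; ai <- hit[, 2]
  same_res <- don$chain_id[di] == acc$chain_id[ai] &
    don$residue_index[di] == acc$residue_index[ai]
  adj_bb <- don$chain_id[di] == acc$chain_id[ai] &
    abs(don$residue_index[di] - acc$residue_index[ai]) == 1 &
    don$atom_name[di] == "N" & acc$atom_name[ai] %in% c("O", "OXT")
  keep <- !same_res & !adj_bb
  di <- di[keep]; ai <- ai[keep]
  if (length(di) == 0) return(empty)

  u <- ante_xyz[di, , drop = FALSE] - dxyz[di, , drop = FALSE]
  v <- axyz[ai, , drop = FALSE] - dxyz[di, , drop = FALSE]
  cosang <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  keep2 <- ang >= angle_min
  di <- di[keep2]; ai <- ai[keep2]; ang <- ang[keep2]
  if (length(di) == 0) return(empty)

  tibble::tibble(
    donor_chain = don$chain_id[di], donor_residue = don$residue_index[di],
    donor_atom = don$atom_name[di],
    acceptor_chain = acc$chain_id[ai], acceptor_residue = acc$residue_index[ai],
    acceptor_atom = acc$atom_name[ai],
    distance = sqrt(rowSums((dxyz[di, , drop = FALSE] -
                               axyz[ai, , drop = FALSE])^2)),
    angle = ang
  ) |>
    dplyr::arrange(.data$donor_chain, .data$donor_residue, .data$donor_atom,
                   .data$acceptor_chain, .data$acceptor_residue,
                   .data$acceptor_atom)
}

# hydrogen bonds across binder <-> peptide in either donor direction,
# deduplicated on the unordered atom pair
hbonds_binder_peptide <- function(x, d_max = 3.5, angle_min = 120) {
  h1 <- detect_hbonds(x, "BINDER", "PEPTIDE", d_max, angle_min)
  h2 <- detect_hbonds(x, "PEPTIDE", "BINDER", d_max, angle_min)
  h <- dplyr::bind_rows(h1, h2)
  if (nrow(h) == 0) return(h)
  key_a <- paste(h$donor_chain, h$donor_residue, h$donor_atom)
  key_b <- paste(h$acceptor_chain, h$acceptor_residue, h$acceptor_atom)
  pair <- ifelse(key_a < key_b, paste(key_a, key_b, sep = "::"),
                 paste(key_b, key_a, sep = "::"))
  h[!duplicated(pair), , drop = FALSE]
}

#' Engagement metrics for one design: how much peptide, how little MHC
#'
#' The core selection statistic of the design funnel. Counts binder–peptide
#' and binder–MHC heavy-atom contacts, the fraction of all binder contacts
#' that involve the peptide, hydrogen bonds across the binder–peptide
#' interface (either donor direction, deduplicated), per-peptide-position
#' contact counts, and `outward_coverage` — the fraction of OUTWARD peptide
#' positions receiving at least `min_contacts_per_position` binder contacts.
#'
#' @param x A [pmhc_complex()] with `BINDER` and `PEPTIDE` chains.
#' @param position_classes Output of [classify_peptide_positions()].
#' @param design_id Label for the output row.
#' @param cutoff Heavy-atom contact cutoff (\enc{Å}{Angstrom}).
#' @param hbond_d_max,hbond_angle_min Hydrogen-bond criteria (see
#'   [detect_hbonds()]).
#' @param min_contacts_per_position Contacts needed for an OUTWARD position
#'   to count as covered.
#' @return One-row tibble: `design_id`, `n_peptide_contacts`,
#'   `n_mhc_contacts`, `peptide_contact_fraction` (`NA` when the binder
#'   makes no contacts at all — never 0/0), `n_hbonds_to_peptide`,
#'   `outward_coverage` (`NA` when no position is OUTWARD), and
#'   `per_position_contacts` (list column: named integer vector, position ->
#'   contact count).
#' @export
engagement_metrics <- function(x, position_classes, design_id = "design",
                               cutoff = 4.5, hbond_d_max = 3.5,
                               hbond_angle_min = 120,
                               min_contacts_per_position = 1L) {
  if (!any(x$atoms$role == "BINDER")) {
    stop("complex has no BINDER chain", call. = FALSE)
  }
  k <- nchar(x$peptide_sequence)
  pep_map <- peptide_positions(x)

  cp_pep <- contact_pairs(x, "BINDER", "PEPTIDE", cutoff)
  n_pep <- nrow(cp_pep)
  n_mhc <- if (any(x$atoms$role == "MHC_HEAVY")) {
    nrow(contact_pairs(x, "BINDER", "MHC_HEAVY", cutoff))
  } else 0L

  per_pos <- stats::setNames(integer(k), as.character(seq_len(k)))
  if (n_pep > 0) {
    pos_of <- stats::setNames(pep_map$position, pep_map$residue_index)
    tab <- table(pos_of[as.character(cp_pep$residue_b)])
    per_pos[names(tab)] <- as.integer(tab)
  }
  frac <- if (n_pep + n_mhc > 0) n_pep / (n_pep + n_mhc) else NA_real_

  nhb <- nrow(hbonds_binder_peptide(x, hbond_d_max, hbond_angle_min))

  outward <- position_classes$position[position_classes$class == "OUTWARD"]
  coverage <- if (length(outward) == 0) NA_real_ else {
    mean(per_pos[as.character(outward)] >= min_contacts_per_position)
  }

  tibble::tibble(
    design_id = design_id,
    n_peptide_contacts = n_pep, n_mhc_contacts = n_mhc,
    peptide_contact_fraction = frac,
    n_hbonds_to_peptide = nhb,
    outward_coverage = coverage,
    per_position_contacts = list(per_pos)
  )
}

#' Triage designs on engagement-metric thresholds
#'
#' A design passes when it meets every minimum; the `reasons` column lists
#' every failed criterion (empty string on pass). An `NA` metric fails its
#' criterion. The default minima are documented heuristics for "extensive
#' peptide contact with limited MHC contact" and should be tuned per
#' campaign.
#'
#' @param metrics Tibble of [engagement_metrics()] rows.
#' @param min_peptide_contacts,min_peptide_contact_fraction,min_outward_coverage,min_hbonds
#'   Threshold minima.
#' @return Tibble `design_id`, `pass`, `reasons` (semicolon-separated).
#' @export
triage_designs <- function(metrics, min_peptide_contacts = 10,
                           min_peptide_contact_fraction = 0.25,
                           min_outward_coverage = 0.5, min_hbonds = 1) {
  check <- function(value, minimum, label) {
    ifelse(!is.na(value) & value >= minimum, NA_character_,
           sprintf("%s < %s", label, format(minimum)))
  }
  res <- metrics |>
    dplyr::mutate(
      r1 = check(.data$n_peptide_contacts, min_peptide_contacts,
                 "n_peptide_contacts"),
      r2 = check(.data$peptide_contact_fraction, min_peptide_contact_fraction,
                 "peptide_contact_fraction"),
      r3 = check(.data$outward_coverage, min_outward_coverage,
                 "outward_coverage"),
      r4 = check(.data$n_hbonds_to_peptide, min_hbonds, "n_hbonds_to_peptide")
    )
  reasons <- purrr::pmap_chr(res[, c("r1", "r2", "r3", "r4")], function(...) {
    paste(stats::na.omit(c(...)), collapse = "; ")
  })
  tibble::tibble(design_id = metrics$design_id,
                 pass = reasons == "", reasons = reasons)
}
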