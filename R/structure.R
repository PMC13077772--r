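# The pmhc_complex container and structure-level operations: reading PDB /
# mmCIF files, role assignment, validation and anchor/outward classification
# of peptide positions.

.chain_roles <- c("MHC_HEAVY", "B2M", "PEPTIDE", "BINDER", "OTHER")

#' Construct a pMHC-I complex from an atom table
#'
#' The central container of the package. Atoms are held as a tibble (one row
#' per atom); each chain carries one role out of `MHC_HEAVY`, `B2M`,
#' `PEPTIDE`, `BINDER`, `OTHER`. The one-letter peptide sequence is derived
#' from the `PEPTIDE` chain in residue-index order.
#'
#' @param atoms Tibble/data frame with columns `chain_id`, `residue_index`,
#'   `residue_name` (3-letter code), `atom_name`, `x`, `y`, `z`, and
#'   optionally `element` and `is_heavy` (derived from `atom_name` when
#'   absent).
#' @param roles Named character vector mapping chain id to role. Chains of
#'   `atoms` not named here are dropped.
#' @param allele Optional HLA allele name, e.g. `"A*02:01"`.
#' @return An object of class `pmhc_complex` with fields `atoms` (tibble),
#'   `roles`, `allele`, `peptide_sequence`.
#' @seealso [read_pmhc()], [validate_complex()]
#' @export
pmhc_complex <- function(atoms, roles, allele = NULL) {
  stopifnot(is.character(roles), !is.null(names(roles)))
  bad_role <- setdiff(unname(roles), .chain_roles)
  if (length(bad_role) > 0) {
    stop("unknown chain role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  atoms <- tibble::as_tibble(atoms)
  missing_chain <- setdiff(names(roles), unique(atoms$chain_id))
  if (length(missing_chain) > 0) {
    stop("role map references absent chain(s): ",
         paste(missing_chain, collapse = ", "), call. = FALSE)
  }
  atoms <- dplyr::filter(atoms, .data$chain_id %in% names(roles))
  if (!"element" %in% names(atoms)) {
    atoms$element <- element_from_atom_name(atoms$atom_name)
  }
  blank <- is.na(atoms$element) | atoms$element == ""
  atoms$element[blank] <- element_from_atom_name(atoms$atom_name[blank])
  atoms$element <- toupper(atoms$element)
  atoms$is_heavy <- atoms$element != "H"
  atoms$residue_index <- as.integer(atoms$residue_index)

  # reject chains containing unmappable residues
  known <- atoms$residue_name %in% c(names(.aa3), names(.aa_modified))
  if (any(!known)) {
    bad <- dplyr::distinct(atoms[!known, ], .data$chain_id, .data$residue_name)
    stop("chain(s) contain unmappable nonstandard residues: ",
         paste(paste0(bad$chain_id, "/", bad$residue_name), collapse = ", "),
         call. = FALSE)
  }
  mod <- atoms$residue_name %in% names(.aa_modified)
  atoms$residue_name[mod] <- unname(.aa_modified[atoms$residue_name[mod]])

  atoms$role <- unname(roles[atoms$chain_id])
  atoms <- dplyr::select(
    atoms, "chain_id", "residue_index", "residue_name", "atom_name",
    "element", "x", "y", "z", "is_heavy", "role"
  )

  pep_chains <- names(roles)[roles == "PEPTIDE"]
  pep_chains <- intersect(pep_chains, unique(atoms$chain_id))
  if (length(pep_chains) == 0) {
    stop("no PEPTIDE chain after filtering", call. = FALSE)
  }
  pep <- atoms |>
    dplyr::filter(.data$role == "PEPTIDE") |>
    dplyr::distinct(.data$chain_id, .data$residue_index, .data$residue_name) |>
    dplyr::arrange(.data$chain_id, .data$residue_index)
  peptide_sequence <- paste(aa_three_to_one(pep$residue_name), collapse = "")

  structure(
    list(atoms = atoms, roles = roles, allele = allele,
         peptide_sequence = peptide_sequence),
    class = "pmhc_complex"
  )
}

#' @export
print.pmhc_complex <- function(x, ...) {
  cat("<pmhc_complex>", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain_id)), "chains\n")
  for (ch in names(x$roles)) {
    n <- sum(x$atoms$chain_id == ch)
    cat(sprintf("  chain %s [%s]: %d atoms\n", ch, x$roles[[ch]], n))
  }
  cat("  peptide:", x$peptide_sequence,
      if (!is.null(x$allele)) paste0("(", x$allele, ")") else "", "\n")
  invisible(x)
}

#' Read a binder/pMHC-I complex from a PDB or mmCIF file
#'
#' Parses the file with \pkg{bio3d}, keeps only the chains named in
#' `role_map`, drops waters and non-polymer heteroatoms, resolves alternate
#' locations to the highest-occupancy conformer (ties broken by file order)
#' and retains a single model from multi-model files.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param role_map Named character vector chain id -> role (see
#'   [pmhc_complex()]).
#' @param model_index Which model to keep from a multi-model file (1-based).
#' @param allele Optional HLA allele annotation.
#' @return A [pmhc_complex()].
#' @export
read_pmhc <- function(path, role_map, model_index = 1L, allele = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- if (is_cif) {
    bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  }
  at <- pdb$atom
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model_index < 1 || model_index > n_models) {
    stop("model_index ", model_index, " out of range (file has ",
         n_models, " model(s))", call. = FALSE)
  }
  if (is.matrix(pdb$xyz) && n_models > 1) {
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }

  # polymer amino-acid records only (drops waters, ions, ligands)
  at <- at[at$resid %in% c(names(.aa3), names(.aa_modified)), , drop = FALSE]
  at <- at[at$chain %in% names(role_map), , drop = FALSE]
  if (nrow(at) == 0) stop("no protein atoms in mapped chains", call. = FALSE)

  # altloc resolution: per (chain, residue, atom), keep highest occupancy,
  # ties -> first occurrence in file order
  at$.ord <- seq_len(nrow(at))
  occ <- if ("o" %in% names(at)) ifelse(is.na(at$o), 1, at$o) else 1
  at$.occ <- occ
  at <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$elety) |>
    dplyr::slice_max(.data$.occ, n = 1, with_ties = TRUE) |>
    dplyr::slice_min(.data$.ord, n = 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord)

  atoms <- tibble::tibble(
    chain_id = at$chain,
    residue_index = as.integer(at$resno),
    residue_name = at$resid,
    atom_name = at$elety,
    element = if ("elesy" %in% names(at)) at$elesy else NA_character_,
    x = at$x, y = at$y, z = at$z
  )
  pmhc_complex(atoms, role_map, allele = allele)
}

#' Write a complex to a PDB file
#'
#' @param x A [pmhc_complex()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pmhc_pdb <- function(x, path) {
  a <- x$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$residue_index, resid = a$residue_name,
    chain = a$chain_id, elety = a$atom_name, elesy = a$element
  )
  invisible(path)
}

#' Check a complex against its structural invariants
#'
#' Diagnostic, never throwing: returns one row per violated invariant
#' (peptide length within 8–11, unique atom keys, finite coordinates,
#' element consistent with atom name, exactly one peptide chain, at most one
#' binder chain). An empty tibble means the complex is valid.
#'
#' @param x A [pmhc_complex()].
#' @return Tibble with columns `invariant`, `detail`.
#' @export
validate_complex <- function(x) {
  v <- list()
  add <- function(invariant, detail) {
    v[[length(v) + 1]] <<- tibble::tibble(invariant = invariant, detail = detail)
  }
  a <- x$atoms

  pep_chains <- unique(a$chain_id[a$role == "PEPTIDE"])
  if (length(pep_chains) != 1) {
    add("one_peptide_chain",
        paste0("found ", length(pep_chains), " PEPTIDE chains"))
  }
  bind_chains <- unique(a$chain_id[a$role == "BINDER"])
  if (length(bind_chains) > 1) {
    add("at_most_one_binder_chain",
        paste0("found ", length(bind_chains), " BINDER chains"))
  }
  k <- nchar(x$peptide_sequence)
  if (length(pep_chains) == 1 && (k < 8 || k > 11)) {
    add("peptide_length_8_to_11", paste0("peptide has ", k, " residues"))
  }
  key <- paste(a$chain_id, a$residue_index, a$atom_name, sep = "|")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    add("unique_atom_key",
        paste0("duplicated (chain, residue, atom): ",
               paste(utils::head(dup, 5), collapse = ", ")))
  }
  bad_xyz <- !is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)
  if (any(bad_xyz)) {
    add("finite_coordinates", paste0(sum(bad_xyz), " atoms with non-finite coords"))
  }
  mismatch <- element_from_atom_name(a$atom_name) != a$element & a$is_heavy
  if (any(mismatch)) {
    add("element_matches_atom_name",
        paste0(sum(mismatch), " atoms where element disagrees with atom name"))
  }
  if (length(v) == 0) {
    tibble::tibble(invariant = character(), detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}

# heavy atoms of the chains holding any of the given roles
role_atoms <- function(x, roles, heavy_only = TRUE) {
  a <- dplyr::filter(x$atoms, .data$role %in% roles)
  if (heavy_only) a <- dplyr::filter(a, .data$is_heavy)
  a
}

# peptide residues in N->C order with a 1-based `position` column
peptide_positions <- function(x) {
  role_atoms(x, "PEPTIDE") |>
    dplyr::distinct(.data$chain_id, .data$residue_index, .data$residue_name) |>
    dplyr::arrange(.data$residue_index) |>
    dplyr::mutate(position = dplyr::row_number())
}

#' Classify peptide positions as groove anchors or outward-facing
#'
#' For each peptide position computes (i) the fraction of side-chain heavy
#' atoms within `contact_cutoff` of any MHC heavy-chain heavy atom (glycine,
#' having no side chain, is assigned fraction 1.0 by convention — it cannot
#' present an outward-facing side chain) and (ii) the relative side-chain
#' solvent accessibility with the binder chain removed, defined as
#' side-chain SASA in the binder-less complex divided by side-chain SASA of
#' the residue extracted in isolation. Positions are then labelled:
#' `ANCHOR` when the contact fraction is at least `anchor_min_fraction`,
#' `OUTWARD` when the fraction is at most `outward_max_fraction` and the
#' relative SASA at least `outward_min_sasa`, otherwise `INTERMEDIATE`.
#'
#' The thresholds are heuristics separating groove-buried from
#' solvent/binder-exposed side chains; no single community convention
#' exists, so all are exposed as arguments.
#'
#' @param x A [pmhc_complex()] with `PEPTIDE` and `MHC_HEAVY` chains. A
#'   `BINDER` chain, if present, is excluded from every computation here.
#' @param contact_cutoff Heavy-atom distance cutoff in \enc{Å}{Angstrom}.
#' @param anchor_min_fraction,outward_max_fraction,outward_min_sasa
#'   Classification thresholds (see above).
#' @param probe_radius,n_sphere_points Passed to [shrake_rupley_sasa()].
#' @return Tibble with one row per peptide position: `position`,
#'   `residue_name`, `class`, `sidechain_mhc_contact_fraction`,
#'   `relative_sidechain_sasa`.
#' @export
classify_peptide_positions <- function(x, contact_cutoff = 4.5,
                                       anchor_min_fraction = 0.5,
                                       outward_max_fraction = 0.2,
                                       outward_min_sasa = 0.2,
                                       probe_radius = 1.4,
                                       n_sphere_points = 240L) {
  if (!any(x$atoms$role == "MHC_HEAVY")) {
    stop("complex has no MHC_HEAVY chain", call. = FALSE)
  }
  nobinder <- strip_role(x, "BINDER")
  pep <- peptide_positions(nobinder)
  mhc_xyz <- as.matrix(role_atoms(nobinder, "MHC_HEAVY")[, c("x", "y", "z")])

  atoms_nb <- dplyr::filter(nobinder$atoms, .data$is_heavy)
  sasa_all <- shrake_rupley_sasa(atoms_nb, probe_radius = probe_radius,
                                 n_sphere_points = n_sphere_points)
  atoms_nb$sasa <- sasa_all

  purrr::pmap_dfr(pep, function(chain_id, residue_index, residue_name, position) {
    res_atoms <- dplyr::filter(
      atoms_nb, .data$chain_id == !!chain_id,
      .data$residue_index == !!residue_index
    )
    sc <- dplyr::filter(res_atoms, !(.data$atom_name %in% .backbone_atoms))
    if (nrow(sc) == 0) {
      frac <- 1.0  # glycine convention
      rel_sasa <- 0.0
    } else {
      sc_xyz <- as.matrix(sc[, c("x", "y", "z")])
      d2 <- cross_dist2(sc_xyz, mhc_xyz)
      in_contact <- apply(d2 <= contact_cutoff^2, 1, any)
      frac <- mean(in_contact)
      iso <- shrake_rupley_sasa(res_atoms, probe_radius = probe_radius,
                                n_sphere_points = n_sphere_points)
      iso_sc <- sum(iso[!(res_atoms$atom_name %in% .backbone_atoms)])
      rel_sasa <- if (iso_sc > 0) sum(sc$sasa) / iso_sc else 0.0
    }
    cls <- if (frac >= anchor_min_fraction) {
      "ANCHOR"
    } else if (frac <= outward_max_fraction && rel_sasa >= outward_min_sasa) {
      "OUTWARD"
    } else {
      "INTERMEDIATE"
    }
    tibble::tibble(
      position = position, residue_name = residue_name, class = cls,
      sidechain_mhc_contact_fraction = frac,
      relative_sidechain_sasa = rel_sasa
    )
  })
}

# drop all chains holding a role; returns a pmhc_complex (PEPTIDE retained)
strip_role <- function(x, role) {
  keep <- x$roles[x$roles != role]
  if (length(keep) == length(x$roles)) return(x)
  pmhc_complex(dplyr::filter(x$atoms, .data$chain_id %in% names(keep)),
               keep, allele = x$allele)
}

# squared Euclidean cross-distance matrix between two n x 3 matrices
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}
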