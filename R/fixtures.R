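# Deterministic generators of toy pMHC-I-like structures and synthetic
# proteomes. The structures are idealized, reduced-detail geometry — two
# groove helices flanking an extended peptide with a binder arcing above —
# built so that the designed contact/anchor/H-bond properties hold by
# construction and can be verified by brute force. They are plausibility
# fixtures, not physical models.

# ideal alpha-helix cylindrical parameters per backbone atom:
# (radius A, phase deg, z-offset A) relative to CA_i at angle twist*i and
# z rise*i. Chosen so that the N(i)...O(i-4) geometry satisfies the
# package's default hydrogen-bond criteria (d <= 3.5 A, donor angle >= 120
# deg) while i-3/i-5 pairs do not.
.helix_atom_params <- list(
  N  = c(1.54, -26.0, -0.90),
  CA = c(2.27,   0.0,  0.00),
  C  = c(1.99,  27.5,  1.05),
  O  = c(1.90,  20.0,  2.40),
  CB = c(3.30,  -6.0, -0.30)
)

# rotation taking the local z axis onto the unit vector `axis`
rotation_to_axis <- function(axis) {
  z <- c(0, 0, 1)
  axis <- axis / sqrt(sum(axis^2))
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  c_ <- sum(z * axis)
  if (sum(v^2) < 1e-12) {
    return(if (c_ > 0) diag(3) else diag(c(1, -1, -1)))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * (1 - c_) / sum(v^2)
}

#' Ideal alpha-helix atom coordinates
#'
#' Builds an ideal helix (rise 1.5 \enc{Å}{Angstrom}/residue, 100
#' degrees/residue by default) with backbone N, CA, C, O and optionally CB,
#' along an arbitrary axis. Deterministic.
#'
#' @param n_res Number of residues.
#' @param origin 3-vector: position of the helix start (axis point at
#'   residue 1).
#' @param axis 3-vector axis direction.
#' @param residue_name `"GLY"` (no CB) or any standard residue (CB added).
#' @param chain_id,first_residue Chain id and starting residue number.
#' @param rise,twist Helical rise (\enc{Å}{Angstrom}) and twist (degrees)
#'   per residue.
#' @return Atom tibble (columns as in [pmhc_complex()] input).
#' @export
make_ideal_helix <- function(n_res, origin = c(0, 0, 0), axis = c(1, 0, 0),
                             residue_name = "ALA", chain_id = "A",
                             first_residue = 1L, rise = 1.5, twist = 100) {
  rot <- rotation_to_axis(axis)
  params <- .helix_atom_params
  if (residue_name == "GLY") params <- params[names(params) != "CB"]
  rows <- purrr::map_dfr(seq_len(n_res), function(i) {
    purrr::imap_dfr(params, function(p, atom) {
      ang <- (twist * i + p[2]) * pi / 180
      local <- c(p[1] * cos(ang), p[1] * sin(ang), rise * i + p[3])
      xyz <- as.numeric(rot %*% local) + origin
      tibble::tibble(
        chain_id = chain_id, residue_index = first_residue + i - 1L,
        residue_name = residue_name, atom_name = atom,
        x = xyz[1], y = xyz[2], z = xyz[3]
      )
    })
  })
  rows
}

#' Specification of a toy pMHC-I fixture
#'
#' Collects the geometric parameters of [make_toy_pmhc()]. The same spec
#' always produces byte-identical structures.
#'
#' @param peptide One-letter peptide sequence, length 8–11.
#' @param anchor_positions Peptide positions whose side chains point down
#'   into the groove (default P2 and the C-terminal position, the common
#'   primary anchors).
#' @param binder Logical: include the toy binder chain.
#' @param binder_contact_positions Peptide positions the binder contacts
#'   (side-chain tip to binder Ser OG); must be non-anchor positions whose
#'   residue has a side-chain tip atom (i.e. not Ala/Gly).
#' @param helix_separation Distance between the two groove-helix axes
#'   (\enc{Å}{Angstrom}).
#' @param peptide_rise Extended-peptide rise per residue
#'   (\enc{Å}{Angstrom}).
#' @param binder_height Height of the binder contact atoms above the
#'   peptide C-alpha plane (\enc{Å}{Angstrom}).
#' @param b2m Logical: include a small decorative beta-2-microglobulin
#'   stand-in chain.
#' @param seed Integer recorded in the spec (the generator itself is fully
#'   deterministic).
#' @return A list of class `toy_pmhc_spec`.
#' @export
toy_spec <- function(peptide = "SLYNTVATL",
                     anchor_positions = c(2L, nchar(peptide)),
                     binder = TRUE,
                     binder_contact_positions = c(4L, 5L, 8L),
                     helix_separation = 12,
                     peptide_rise = 3.5,
                     binder_height = 6.3,
                     b2m = TRUE,
                     seed = 1L) {
  k <- nchar(peptide)
  stopifnot(k >= 8, k <= 11)
  stopifnot(all(anchor_positions >= 1), all(anchor_positions <= k))
  if (binder) {
    stopifnot(all(binder_contact_positions >= 1),
              all(binder_contact_positions <= k))
    if (any(binder_contact_positions %in% anchor_positions)) {
      stop("binder contact positions must be non-anchor", call. = FALSE)
    }
  }
  structure(
    list(peptide = peptide, anchor_positions = as.integer(anchor_positions),
         binder = binder,
         binder_contact_positions = as.integer(binder_contact_positions),
         helix_separation = helix_separation, peptide_rise = peptide_rise,
         binder_height = binder_height, b2m = b2m, seed = as.integer(seed)),
    class = "toy_pmhc_spec"
  )
}

# reduced-detail peptide residue: backbone N/CA/C/O, CB and one tip
# pseudo-atom along +-z (the outward/inward normal)
toy_peptide_atoms <- function(spec) {
  k <- nchar(spec$peptide)
  letters_pep <- strsplit(spec$peptide, "")[[1]]
  res3 <- aa_one_to_three(letters_pep)
  purrr::map_dfr(seq_len(k), function(i) {
    ca <- c((i - (k + 1) / 2) * spec$peptide_rise, 0, 2.5)
    dirz <- if (i %in% spec$anchor_positions) -1 else 1
    rows <- tibble::tribble(
      ~atom_name, ~x, ~y, ~z,
      "N", ca[1] - 1.25, ca[2] + 0.9, ca[3],
      "CA", ca[1], ca[2], ca[3],
      "C", ca[1] + 1.25, ca[2] + 0.9, ca[3],
      "O", ca[1] + 1.25, ca[2] + 2.1, ca[3]
    )
    if (res3[i] != "GLY") {
      rows <- dplyr::bind_rows(
        rows,
        tibble::tibble(atom_name = "CB", x = ca[1], y = ca[2],
                       z = ca[3] + dirz * 1.5)
      )
      tip <- .sidechain_tip[res3[i]]
      if (!is.na(tip)) {
        rows <- dplyr::bind_rows(
          rows,
          tibble::tibble(atom_name = unname(tip), x = ca[1], y = ca[2],
                         z = ca[3] + dirz * 3.0)
        )
      }
    }
    dplyr::mutate(rows, chain_id = "C", residue_index = i,
                  residue_name = res3[i])
  })
}

#' Generate a deterministic toy binder/pMHC-I complex
#'
#' Geometry (all \enc{Å}{Angstrom}): an extended peptide runs along x at
#' z = 2.5, flanked by two antiparallel ideal poly-Gly helices (the groove
#' walls, chain A = MHC heavy) whose axes lie at y = ±`helix_separation`/2,
#' z = -1. Anchor-position side chains point down into the groove (within
#' contact range of the helices); all other side chains point up into
#' solvent. The optional binder (chain D) is a poly-Ala helix high above
#' the peptide plus one serine "reader" residue per designated contact
#' position, whose OG sits directly above that position's side-chain tip —
#' close enough for a contact and a hydrogen bond (when the tip is polar),
#' and too far from every other position. A decorative B2M stand-in helix
#' (chain B) sits below the groove. The output is a pure function of the
#' spec.
#'
#' @param spec A [toy_spec()].
#' @return A [pmhc_complex()] with roles A = MHC_HEAVY, B = B2M (optional),
#'   C = PEPTIDE, D = BINDER (optional).
#' @export
make_toy_pmhc <- function(spec) {
  stopifnot(inherits(spec, "toy_pmhc_spec"))
  k <- nchar(spec$peptide)
  half_span <- (k - 1) / 2 * spec$peptide_rise + 3

  pep <- toy_peptide_atoms(spec)

  n_helix <- ceiling(2 * half_span / 1.5) + 1
  sep <- spec$helix_separation / 2
  h1 <- make_ideal_helix(n_helix, origin = c(-half_span, -sep, -1),
                         axis = c(1, 0, 0), residue_name = "GLY",
                         chain_id = "A", first_residue = 1L)
  h2 <- make_ideal_helix(n_helix, origin = c(half_span, sep, -1),
                         axis = c(-1, 0, 0), residue_name = "GLY",
                         chain_id = "A",
                         first_residue = n_helix + 1L)
  mhc <- dplyr::bind_rows(h1, h2)

  # groove-overlap guard: helices must not run through the peptide
  pep_ca <- as.matrix(dplyr::filter(pep, .data$atom_name == "CA")[, c("x", "y", "z")])
  d2 <- cross_dist2(pep_ca, as.matrix(mhc[, c("x", "y", "z")]))
  if (min(d2) < 2^2) {
    stop("invalid geometry: groove helices overlap the peptide", call. = FALSE)
  }

  chains <- list(mhc, pep)
  roles <- c(A = "MHC_HEAVY", C = "PEPTIDE")

  if (spec$b2m) {
    b2m <- make_ideal_helix(8, origin = c(-6, 0, -10), axis = c(1, 0, 0),
                            residue_name = "GLY", chain_id = "B")
    chains <- c(chains, list(b2m))
    roles <- c(roles, B = "B2M")
  }

  if (spec$binder) {
    res3 <- aa_one_to_three(strsplit(spec$peptide, "")[[1]])
    bad <- spec$binder_contact_positions[
      res3[spec$binder_contact_positions] %in% c("GLY", "ALA")]
    if (length(bad) > 0) {
      stop("binder contact positions need a side-chain tip atom; ",
           "positions ", paste(bad, collapse = ", "), " are Gly/Ala",
           call. = FALSE)
    }
    support <- make_ideal_helix(n_helix, origin = c(-half_span, 0, 16),
                                axis = c(1, 0, 0), residue_name = "ALA",
                                chain_id = "D", first_residue = 1L)
    og_z <- 2.5 + spec$binder_height
    readers <- purrr::map_dfr(seq_along(spec$binder_contact_positions),
                              function(j) {
      p <- spec$binder_contact_positions[j]
      xp <- (p - (k + 1) / 2) * spec$peptide_rise
      tibble::tibble(
        chain_id = "D",
        residue_index = n_helix + j,
        residue_name = "SER",
        atom_name = c("N", "CA", "C", "O", "CB", "OG"),
        x = xp + c(-1.2, 0, 1.2, 1.2, 0, 0),
        y = c(0.6, 0, 0.6, 1.8, 0, 0),
        z = og_z + c(2.4, 2.4, 2.4, 2.4, 1.5, 0)
      )
    })
    chains <- c(chains, list(support, readers))
    roles <- c(roles, D = "BINDER")
  }

  pmhc_complex(dplyr::bind_rows(chains), roles)
}

#' Add Gaussian coordinate noise to a complex
#'
#' Independent zero-mean normal noise with standard deviation `sigma` per
#' coordinate on every atom; deterministic per seed; `sigma = 0` returns an
#' identical copy. The global RNG state is left untouched.
#'
#' @param x A [pmhc_complex()].
#' @param sigma Noise scale in \enc{Å}{Angstrom}, >= 0.
#' @param seed Integer seed.
#' @return A perturbed [pmhc_complex()].
#' @export
perturb_coords <- function(x, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(x)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  n <- nrow(x$atoms)
  noise <- matrix(stats::rnorm(3 * n, 0, sigma), ncol = 3)
  atoms <- x$atoms
  atoms$x <- atoms$x + noise[, 1]
  atoms$y <- atoms$y + noise[, 2]
  atoms$z <- atoms$z + noise[, 3]
  pmhc_complex(atoms, x$roles, allele = x$allele)
}

#' Generate a synthetic proteome with planted peptides
#'
#' Uniform-random amino-acid sequences (or a supplied background
#' frequency) with known substrings overwritten at stated loci, for
#' planted-truth testing of the cross-reactivity scan. Deterministic per
#' seed; the global RNG state is left untouched.
#'
#' @param n_proteins,protein_length Proteome dimensions.
#' @param seed Integer seed.
#' @param planted Optional tibble/data frame with columns `sequence`,
#'   `protein_index`, `offset` (1-based). Planted loci must fit inside
#'   their protein and must not overlap each other.
#' @param frequencies Optional named residue sampling weights (default
#'   uniform over the 20 standard letters).
#' @return A `Biostrings::AAStringSet` named `protein_001`, ...
#' @export
make_synthetic_proteome <- function(n_proteins, protein_length, seed = 1L,
                                    planted = NULL, frequencies = NULL) {
  aa <- sort(names(.aa1))
  prob <- if (is.null(frequencies)) NULL else {
    stopifnot(all(aa %in% names(frequencies)))
    unname(frequencies[aa])
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  seqs <- vapply(seq_len(n_proteins), function(i) {
    paste(sample(aa, protein_length, replace = TRUE, prob = prob),
          collapse = "")
  }, character(1))

  if (!is.null(planted) && nrow(planted) > 0) {
    planted <- tibble::as_tibble(planted)
    stopifnot(all(c("sequence", "protein_index", "offset") %in% names(planted)))
    ends <- planted$offset + nchar(planted$sequence) - 1
    if (any(planted$protein_index < 1 | planted$protein_index > n_proteins) ||
        any(planted$offset < 1) || any(ends > protein_length)) {
      stop("planted locus out of range", call. = FALSE)
    }
    by_prot <- split(seq_len(nrow(planted)), planted$protein_index)
    for (idx in by_prot) {
      iv <- cbind(planted$offset[idx], ends[idx])
      if (length(idx) > 1) {
        o <- order(iv[, 1])
        if (any(iv[o, 1][-1] <= iv[o, 2][-length(idx)])) {
          stop("overlapping planted loci", call. = FALSE)
        }
      }
    }
    for (i in seq_len(nrow(planted))) {
      p <- planted$protein_index[i]
      substr(seqs[p], planted$offset[i], ends[i]) <- planted$sequence[i]
    }
  }
  Biostrings::AAStringSet(stats::setNames(
    seqs, sprintf("protein_%03d", seq_len(n_proteins))))
}
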