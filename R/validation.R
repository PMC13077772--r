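# Structural and functional validation analytics: Kabsch superposition,
# model-vs-crystal comparison, CD69 activation summaries and NGS sort
# enrichment.

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation (reflections excluded) and translation
#' minimizing the RMSD between corresponding points; correspondence is by
#' row order. The SVD route: with both sets centered, the rotation is
#' `V diag(1, 1, det(V U')) U'` from the SVD of the covariance matrix.
#'
#' @param mobile,reference Numeric n x 3 matrices, n >= 3, equal n.
#' @return Object of class `kabsch_superposition`: `rotation` (3 x 3,
#'   det +1), `translation` (length 3; transformed = mobile %*% t(rotation)
#'   + translation), `rmsd`, `n_atoms`, `transformed` (the fitted mobile
#'   coordinates), `degenerate` (TRUE when the point sets are collinear and
#'   the rotation is not unique). Supports [tidy()] (per-atom deviations)
#'   and [glance()].
#' @export
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' fit <- kabsch_superpose(x, x)
#' fit$rmsd  # 0
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    stop("mobile and reference must be equal-size n x 3 matrices",
         call. = FALSE)
  }
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm); R <- sweep(reference, 2, cr)
  H <- crossprod(M, R)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  degenerate <- s$d[2] < 1e-8 * max(s$d[1], 1e-12)
  transformed <- M %*% t(rot)
  rmsd <- sqrt(mean(rowSums((transformed - R)^2)))
  transformed <- sweep(transformed, 2, cr, "+")
  structure(
    list(rotation = rot, translation = as.numeric(cr - rot %*% cm),
         rmsd = rmsd, n_atoms = n, transformed = transformed,
         degenerate = degenerate),
    class = "kabsch_superposition"
  )
}

#' @export
print.kabsch_superposition <- function(x, ...) {
  cat(sprintf("<kabsch_superposition> %d atoms, rmsd %.4f A%s\n",
              x$n_atoms, x$rmsd,
              if (x$degenerate) " (degenerate/collinear set)" else ""))
  invisible(x)
}

#' Turn a superposition fit into a tidy per-atom table
#'
#' @param x A `kabsch_superposition`.
#' @param reference Optional reference coordinates; when given, a
#'   `deviation` column (per-atom distance after fitting) is included.
#' @param ... Unused.
#' @return Tibble of fitted coordinates (and deviations).
#' @export
tidy.kabsch_superposition <- function(x, reference = NULL, ...) {
  out <- tibble::as_tibble(x$transformed, .name_repair = ~c("x", "y", "z"))
  out$atom <- seq_len(nrow(out))
  if (!is.null(reference)) {
    out$deviation <- sqrt(rowSums((x$transformed - as.matrix(reference))^2))
  }
  dplyr::relocate(out, "atom")
}

#' One-row summary of a superposition fit
#'
#' @param x A `kabsch_superposition`.
#' @param ... Unused.
#' @return Tibble with `rmsd`, `n_atoms`, `rotation_det`, `degenerate`.
#' @export
glance.kabsch_superposition <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n_atoms = x$n_atoms,
                 rotation_det = det(x$rotation), degenerate = x$degenerate)
}

#' Generic tidy/glance (broom-style)
#' @param x Object to summarise.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Binder residues at the interface with peptide or MHC
#'
#' @param x A [pmhc_complex()] with a `BINDER` chain.
#' @param cutoff Heavy-atom distance cutoff (\enc{Å}{Angstrom}).
#' @return Tibble `chain_id`, `residue_index` of binder residues having any
#'   heavy atom within `cutoff` of any peptide or MHC heavy-chain heavy
#'   atom.
#' @export
interface_residue_set <- function(x, cutoff = 4.5) {
  bnd <- role_atoms(x, "BINDER")
  if (nrow(bnd) == 0) stop("complex has no BINDER chain", call. = FALSE)
  tgt <- role_atoms(x, c("PEPTIDE", "MHC_HEAVY"))
  empty <- tibble::tibble(chain_id = character(), residue_index = integer())
  if (cutoff <= 0 || nrow(tgt) == 0) return(empty)
  d2 <- cross_dist2(as.matrix(bnd[, c("x", "y", "z")]),
                    as.matrix(tgt[, c("x", "y", "z")]))
  near <- apply(d2 <= cutoff^2, 1, any)
  bnd[near, c("chain_id", "residue_index")] |>
    dplyr::distinct() |>
    dplyr::arrange(.data$chain_id, .data$residue_index)
}

# atoms shared by two complexes, paired on (role, residue_index, atom_name);
# returns list(a = matrix, b = matrix, key = tibble)
shared_atoms <- function(a, b, roles = NULL, atom_names = NULL,
                         residues = NULL) {
  pick <- function(x) {
    at <- dplyr::filter(x$atoms, .data$is_heavy)
    if (!is.null(roles)) at <- dplyr::filter(at, .data$role %in% roles)
    if (!is.null(atom_names)) {
      at <- dplyr::filter(at, .data$atom_name %in% atom_names)
    }
    if (!is.null(residues)) {
      at <- dplyr::semi_join(at, residues, by = c("role", "residue_index"))
    }
    at
  }
  aa <- pick(a); bb <- pick(b)
  j <- dplyr::inner_join(
    aa, bb, by = c("role", "residue_index", "atom_name"),
    suffix = c("_a", "_b"), relationship = "one-to-one"
  )
  list(
    a = as.matrix(j[, c("x_a", "y_a", "z_a")]),
    b = as.matrix(j[, c("x_b", "y_b", "z_b")]),
    key = j[, c("role", "residue_index", "atom_name")]
  )
}

#' Compare a design model with a crystal (or other reference) structure
#'
#' Two complementary accuracy measures, mirroring how designed-binder
#' structures are usually benchmarked: (i) backbone accuracy — RMSD over
#' binder C-alpha atoms after Kabsch superposition on those same atoms; and
#' (ii) side-chain/interface accuracy — all-heavy-atom RMSD over the
#' model-defined interface residues (binder residues within
#' `interface_cutoff` of peptide or MHC) after superposition on that atom
#' set. Residues are paired by residue index within role-matched chains;
#' atoms present in only one structure are reported and excluded.
#'
#' @param model,crystal [pmhc_complex()] objects with pairable numbering.
#' @param interface_cutoff Cutoff defining the model interface set
#'   (\enc{Å}{Angstrom}).
#' @param frame Superposition frame for the backbone measure:
#'   `"binder_ca"` (default; fit and measure on binder C-alphas) or
#'   `"mhc_ca"` (fit on MHC-heavy C-alphas, measure binder C-alphas).
#' @return One-row tibble: `ca_rmsd_binder`, `interface_allatom_rmsd`,
#'   `n_interface_residues`, `n_ca_paired`, `n_interface_atoms`,
#'   `n_unpaired_atoms`.
#' @export
compare_model_to_crystal <- function(model, crystal, interface_cutoff = 4.5,
                                     frame = c("binder_ca", "mhc_ca")) {
  frame <- match.arg(frame)
  ca <- shared_atoms(model, crystal, roles = "BINDER", atom_names = "CA")
  if (nrow(ca$a) == 0) stop("no pairable binder C-alpha atoms", call. = FALSE)
  if (frame == "binder_ca") {
    fit <- kabsch_superpose(ca$a, ca$b)
    ca_rmsd <- fit$rmsd
  } else {
    fr <- shared_atoms(model, crystal, roles = "MHC_HEAVY", atom_names = "CA")
    if (nrow(fr$a) == 0) stop("no pairable MHC C-alpha atoms", call. = FALSE)
    fit <- kabsch_superpose(fr$a, fr$b)
    moved <- sweep(ca$a %*% t(fit$rotation), 2, fit$translation, "+")
    ca_rmsd <- sqrt(mean(rowSums((moved - ca$b)^2)))
  }

  iface <- interface_residue_set(model, interface_cutoff)
  if (nrow(iface) == 0) stop("model interface set is empty", call. = FALSE)
  iface_key <- model$atoms |>
    dplyr::distinct(.data$chain_id, .data$residue_index, .data$role) |>
    dplyr::semi_join(iface, by = c("chain_id", "residue_index")) |>
    dplyr::select("role", "residue_index")
  ia <- shared_atoms(model, crystal, roles = "BINDER", residues = iface_key)
  if (nrow(ia$a) < 3) stop("fewer than 3 shared interface atoms", call. = FALSE)
  iface_fit <- kabsch_superpose(ia$a, ia$b)

  n_model <- sum(model$atoms$is_heavy & model$atoms$role == "BINDER")
  n_cryst <- sum(crystal$atoms$is_heavy & crystal$atoms$role == "BINDER")
  n_shared <- nrow(shared_atoms(model, crystal, roles = "BINDER")$a)
  tibble::tibble(
    ca_rmsd_binder = ca_rmsd,
    interface_allatom_rmsd = iface_fit$rmsd,
    n_interface_residues = nrow(iface),
    n_ca_paired = nrow(ca$a),
    n_interface_atoms = nrow(ia$a),
    n_unpaired_atoms = n_model + n_cryst - 2L * n_shared
  )
}

#' Summarise a CD69 activation (MFI) table
#'
#' @param tbl Tibble with columns `condition`, `replicate`, `mfi`.
#' @param control_label The reference condition (e.g. `"DMSO"`), which must
#'   be present with nonzero mean MFI.
#' @return Tibble per condition: `n`, `mean_mfi`, `sd_mfi` (sample SD; 0
#'   for single replicates), `fold_over_control`.
#' @export
activation_summary <- function(tbl, control_label = "DMSO") {
  stopifnot(all(c("condition", "mfi") %in% names(tbl)))
  if (!control_label %in% tbl$condition) {
    stop("control condition '", control_label, "' not in table",
         call. = FALSE)
  }
  if (any(!is.finite(tbl$mfi)) || any(tbl$mfi < 0)) {
    stop("MFI values must be finite and non-negative", call. = FALSE)
  }
  out <- tbl |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_mfi = mean(.data$mfi),
      sd_mfi = ifelse(dplyr::n() > 1, stats::sd(.data$mfi), 0),
      .groups = "drop"
    )
  ctrl <- out$mean_mfi[out$condition == control_label]
  if (ctrl == 0) stop("control mean MFI is zero", call. = FALSE)
  dplyr::mutate(out, fold_over_control = .data$mean_mfi / ctrl)
}

#' Sort enrichment from pre/post selection sequencing counts
#'
#' `log2((f_post + p) / (f_pre + p))` per design, with frequencies
#' `f = count / total` and pseudocount `p > 0` bounding designs absent from
#' one pool. Designs present in only one pool get count 0 in the other.
#' The default pseudocount is Jeffreys-style, `0.5 / mean(total_pre,
#' total_post)`; pass an explicit `p` for exact scale invariance across
#' sequencing depths.
#'
#' @param counts_pre,counts_post Named non-negative integer vectors,
#'   design -> read count.
#' @param pseudocount Positive frequency-scale pseudocount, or `NULL` for
#'   the default above.
#' @return Tibble `design_id`, `count_pre`, `count_post`,
#'   `log2_enrichment`, sorted by enrichment descending.
#' @export
sort_enrichment <- function(counts_pre, counts_post, pseudocount = NULL) {
  ids <- sort(union(names(counts_pre), names(counts_post)))
  if (length(ids) == 0) stop("no designs in either pool", call. = FALSE)
  pre <- ifelse(ids %in% names(counts_pre), counts_pre[ids], 0)
  post <- ifelse(ids %in% names(counts_post), counts_post[ids], 0)
  if (any(pre < 0) || any(post < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  tp <- sum(pre); tq <- sum(post)
  if (tp == 0 && tq == 0) stop("both pools have zero total", call. = FALSE)
  if (is.null(pseudocount)) pseudocount <- 0.5 / mean(c(tp, tq))
  stopifnot(pseudocount > 0)
  f_pre <- if (tp > 0) pre / tp else rep(0, length(pre))
  f_post <- if (tq > 0) post / tq else rep(0, length(post))
  tibble::tibble(
    design_id = ids,
    count_pre = as.integer(pre), count_post = as.integer(post),
    log2_enrichment = log2((f_post + pseudocount) / (f_pre + pseudocount))
  ) |>
    dplyr::arrange(dplyr::desc(.data$log2_enrichment), .data$design_id)
}
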