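# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (plain double loops over atom rows) so they share no
# code path with the package implementations they check.

toy_default <- function(...) make_toy_pmhc(toy_spec(...))

# a randomized-but-deterministic toy spec; peptide letters drawn from
# residues that carry a side-chain tip so any position can be a binder
# contact
random_toy_spec <- function(seed) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    k <- sample(8:11, 1)
    letters_ok <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                          c("A", "G"))
    pep <- paste(sample(letters_ok, k, replace = TRUE), collapse = "")
    anchors <- c(2L, k)
    n_contact <- sample(2:3, 1)
    contacts <- sort(sample(setdiff(seq_len(k), anchors), n_contact))
    toy_spec(peptide = pep, anchor_positions = anchors,
             binder_contact_positions = contacts,
             helix_separation = sample(c(11, 12, 13), 1), seed = seed)
  })
}

atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

# all heavy-atom pairs across two roles within cutoff, by explicit loop
oracle_contact_pairs <- function(cx, role_a, role_b, cutoff) {
  a <- as.data.frame(subset(cx$atoms, role %in% role_a & is_heavy))
  b <- as.data.frame(subset(cx$atoms, role %in% role_b & is_heavy))
  rows <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (d <= cutoff) {
        rows[[length(rows) + 1]] <- data.frame(
          chain_a = a$chain_id[i], residue_a = a$residue_index[i],
          atom_a = a$atom_name[i],
          chain_b = b$chain_id[j], residue_b = b$residue_index[j],
          atom_b = b$atom_name[j], distance = d
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chain_a = character(), residue_a = integer(),
                      atom_a = character(), chain_b = character(),
                      residue_b = integer(), atom_b = character(),
                      distance = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$chain_a, out$residue_a, out$atom_a, out$chain_b,
            out$residue_b, out$atom_b), , drop = FALSE]
}

# binder residues within cutoff of peptide/MHC, by explicit loop
oracle_interface_residues <- function(cx, cutoff) {
  bnd <- as.data.frame(subset(cx$atoms, role == "BINDER" & is_heavy))
  tgt <- as.data.frame(subset(cx$atoms,
                              role %in% c("PEPTIDE", "MHC_HEAVY") & is_heavy))
  keep <- character()
  for (i in seq_len(nrow(bnd))) {
    for (j in seq_len(nrow(tgt))) {
      d <- sqrt((bnd$x[i] - tgt$x[j])^2 + (bnd$y[i] - tgt$y[j])^2 +
                  (bnd$z[i] - tgt$z[j])^2)
      if (d <= cutoff) {
        keep <- c(keep, paste(bnd$chain_id[i], bnd$residue_index[i]))
        break
      }
    }
  }
  sort(unique(keep))
}

# numerical rigid-transform optimizer: minimum RMSD over rotations (Euler
# angles) and translations, multiple restarts
oracle_min_rmsd <- function(mobile, reference, n_starts = 8) {
  rot_from_euler <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(p) {
    R <- rot_from_euler(p[1:3])
    t <- p[4:6]
    moved <- sweep(mobile %*% t(R), 2, t, "+")
    sqrt(mean(rowSums((moved - reference)^2)))
  }
  best <- Inf
  set.seed(99)
  starts <- rbind(rep(0, 6),
                  matrix(stats::runif(6 * (n_starts - 1), -pi, pi),
                         ncol = 6))
  starts[, 4:6] <- starts[, 4:6] / pi  # modest translation starts
  for (s in seq_len(nrow(starts))) {
    r1 <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-14))
    r2 <- stats::optim(r1$par, obj, method = "BFGS",
                       control = list(maxit = 1000, reltol = 1e-14))
    best <- min(best, r1$value, r2$value)
  }
  best
}

# naive hydrogen-bond enumeration between two role groups: explicit loops
# over donor/acceptor candidates derived afresh from the packaged chemistry
# tables, with the same geometric criteria
oracle_hbonds <- function(cx, donor_role, acceptor_role, d_max = 3.5,
                          angle_min = 120) {
  at <- as.data.frame(subset(cx$atoms, is_heavy))
  sd_tab <- as.data.frame(pepmhc:::.hbond_sidechain_donors)
  sa_tab <- as.data.frame(pepmhc:::.hbond_sidechain_acceptors)
  don <- at[at$role %in% donor_role &
              ((at$atom_name == "N" & at$residue_name != "PRO") |
                 paste(at$residue_name, at$atom_name) %in%
                 paste(sd_tab$residue_name, sd_tab$atom_name)), ]
  acc <- at[at$role %in% acceptor_role &
              (at$atom_name %in% c("O", "OXT") |
                 paste(at$residue_name, at$atom_name) %in%
                 paste(sa_tab$residue_name, sa_tab$atom_name)), ]
  n_bonds <- 0L
  for (i in seq_len(nrow(don))) {
    res <- at[at$chain_id == don$chain_id[i] &
                at$residue_index == don$residue_index[i], ]
    ante_name <- if (don$atom_name[i] == "N") "CA" else
      sd_tab$antecedent[sd_tab$residue_name == don$residue_name[i] &
                          sd_tab$atom_name == don$atom_name[i]][1]
    ante <- NULL
    for (cand in unique(c(ante_name, "CB", "CA"))) {
      hit <- res[res$atom_name == cand, ]
      if (nrow(hit) > 0) { ante <- as.numeric(hit[1, c("x", "y", "z")]); break }
    }
    if (is.null(ante)) next
    dxyz <- as.numeric(don[i, c("x", "y", "z")])
    for (j in seq_len(nrow(acc))) {
      same_res <- don$chain_id[i] == acc$chain_id[j] &&
        don$residue_index[i] == acc$residue_index[j]
      adj_bb <- don$chain_id[i] == acc$chain_id[j] &&
        abs(don$residue_index[i] - acc$residue_index[j]) == 1 &&
        don$atom_name[i] == "N" && acc$atom_name[j] %in% c("O", "OXT")
      if (same_res || adj_bb) next
      axyz <- as.numeric(acc[j, c("x", "y", "z")])
      d <- sqrt(sum((dxyz - axyz)^2))
      if (d > d_max) next
      u <- ante - dxyz; v <- axyz - dxyz
      ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
      if (ang >= angle_min) n_bonds <- n_bonds + 1L
    }
  }
  n_bonds
}

# direct character-loop identity count
oracle_identity_count <- function(a, b) {
  sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

# rigid transform of a complex (rotation about a random axis + shift)
rigid_transform <- function(cx, seed = 1) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  shift <- stats::rnorm(3, 0, 20)
  atoms <- cx$atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  pmhc_complex(atoms, cx$roles, allele = cx$allele)
}
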