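# Shrake-Rupley solvent-accessible surface area on a deterministic
# Fibonacci sphere lattice. Pure R; the structures this package handles are
# small enough (a few thousand heavy atoms) that no neighbour grid is needed.

# n approximately evenly distributed unit vectors (golden-angle spiral);
# deterministic for fixed n
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake–Rupley solvent-accessible surface area
#'
#' Per-atom SASA by the rolling-probe lattice method: each heavy atom is
#' covered with `n_sphere_points` points at its probe-expanded radius
#' (deterministic Fibonacci lattice) and a point is accessible when it lies
#' outside the probe-expanded sphere of every other atom. Each accessible
#' point contributes 4*pi*(radius + probe)^2 / n_sphere_points
#' \enc{Å}{Angstrom}². Hydrogens are ignored.
#'
#' @param x A [pmhc_complex()] or an atom tibble with columns `element`,
#'   `x`, `y`, `z` (and optionally `is_heavy`).
#' @param probe_radius Probe sphere radius in \enc{Å}{Angstrom} (water:
#'   1.4).
#' @param n_sphere_points Lattice points per atom (>= 60); more points,
#'   finer area resolution.
#' @param radii Named per-element van der Waals radii; defaults to
#'   [default_vdw_radii()]. An element absent from the table is an error.
#' @return Numeric vector of per-atom SASA in \enc{Å}{Angstrom}², in atom
#'   order (heavy atoms only when `x` is a complex; when `x` is a tibble
#'   containing hydrogens they receive `NA`).
#' @export
#' @examples
#' a <- tibble::tibble(element = "C", x = 0, y = 0, z = 0)
#' shrake_rupley_sasa(a)          # ~ 4*pi*(1.7+1.4)^2
shrake_rupley_sasa <- function(x, probe_radius = 1.4, n_sphere_points = 240L,
                               radii = default_vdw_radii()) {
  atoms <- if (inherits(x, "pmhc_complex")) {
    dplyr::filter(x$atoms, .data$is_heavy)
  } else {
    tibble::as_tibble(x)
  }
  if (n_sphere_points < 60) {
    stop("n_sphere_points must be >= 60", call. = FALSE)
  }
  heavy <- if ("is_heavy" %in% names(atoms)) atoms$is_heavy else
    rep(TRUE, nrow(atoms))
  el <- atoms$element[heavy]
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown) > 0) {
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  xyz <- as.matrix(atoms[heavy, c("x", "y", "z")])
  r <- unname(radii[el]) + probe_radius
  n <- nrow(xyz)
  pts <- fibonacci_sphere(n_sphere_points)
  sasa <- numeric(n)
  if (n == 1) {
    sasa[1] <- 4 * pi * r[1]^2
  } else {
    d2 <- cross_dist2(xyz, xyz)
    for (i in seq_len(n)) {
      # neighbours whose expanded sphere can intersect atom i's shell
      nb <- which(d2[i, ] < (r[i] + r)^2)
      nb <- nb[nb != i]
      shell <- sweep(pts * r[i], 2, xyz[i, ], "+")
      if (length(nb) == 0) {
        acc <- n_sphere_points
      } else {
        pd2 <- cross_dist2(shell, xyz[nb, , drop = FALSE])
        buried <- pd2 <= matrix(r[nb]^2, nrow = n_sphere_points,
                                ncol = length(nb), byrow = TRUE)
        acc <- sum(!apply(buried, 1, any))
      }
      sasa[i] <- 4 * pi * r[i]^2 * acc / n_sphere_points
    }
  }
  if (all(heavy)) sasa else {
    out <- rep(NA_real_, nrow(atoms)); out[heavy] <- sasa; out
  }
}
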