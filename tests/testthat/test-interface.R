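# two single-atom "chains" at a controllable separation
two_atom_complex <- function(gap) {
  atoms <- tibble::tibble(
    chain_id = c("C", rep("C", 7), "D"),
    residue_index = c(1:8, 1L),
    residue_name = "GLY",
    atom_name = "CA",
    x = c(seq(0, by = 3.5, length.out = 8), 0),
    y = 0,
    z = c(rep(0, 8), gap)
  )
  pmhc_complex(atoms, c(C = "PEPTIDE", D = "BINDER"))
}

test_that("contact_pairs honors the cutoff and rejects bad groups", {
  far <- two_atom_complex(10)
  expect_equal(nrow(contact_pairs(far, "BINDER", "PEPTIDE", 4.5)), 0)

  near <- two_atom_complex(3)
  cp <- contact_pairs(near, "BINDER", "PEPTIDE", 4.5)
  expect_equal(nrow(cp), 1)
  expect_equal(cp$distance, 3.0)

  expect_error(contact_pairs(near, "PEPTIDE", "PEPTIDE", 4.5), "overlap")
  expect_error(contact_pairs(near, "BINDER", "B2M", 4.5), "no atoms")
  expect_error(contact_pairs(near, "BINDER", "PEPTIDE", -1))
})

test_that("contact_pairs equals the double-loop oracle and is symmetric", {
  for (seed in c(1, 7, 42)) {
    cx <- make_toy_pmhc(random_toy_spec(seed))
    cp <- contact_pairs(cx, "BINDER", "PEPTIDE", 4.5)
    orc <- oracle_contact_pairs(cx, "BINDER", "PEPTIDE", 4.5)
    expect_equal(nrow(cp), nrow(orc))
    expect_equal(cp$distance, orc$distance, tolerance = 1e-12)
    expect_equal(paste(cp$chain_a, cp$residue_a, cp$atom_a),
                 paste(orc$chain_a, orc$residue_a, orc$atom_a))

    # symmetry: swapped groups give the same unordered pair set
    sw <- contact_pairs(cx, "PEPTIDE", "BINDER", 4.5)
    key1 <- sort(paste(cp$chain_a, cp$residue_a, cp$atom_a, "::",
                       cp$chain_b, cp$residue_b, cp$atom_b))
    key2 <- sort(paste(sw$chain_b, sw$residue_b, sw$atom_b, "::",
                       sw$chain_a, sw$residue_a, sw$atom_a))
    expect_equal(key1, key2)
  }
})

test_that("pair count is monotone in the cutoff", {
  cx <- toy_default()
  counts <- vapply(c(3, 3.5, 4, 4.5, 5, 6, 8),
                   function(ct) nrow(contact_pairs(cx, "BINDER", "PEPTIDE", ct)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("hydrogen-bond criteria: distance, angle, adjacency exclusion", {
  # backbone N donor (antecedent CA at +x) and O acceptor placed at -x from
  # the first N, so the donor geometry is linear (angle 180)
  mk <- function(no_dist) {
    atoms <- tibble::tibble(
      chain_id = c(rep("C", 9 * 2), "D", "D"),
      residue_index = c(rep(1:9, each = 2), 1L, 1L),
      residue_name = c(rep("ALA", 18), "ALA", "ALA"),
      atom_name = c(rep(c("N", "CA"), 9), "O", "C"),
      x = c(rep(seq(0, by = 3.5, length.out = 9), each = 2) +
              rep(c(0, 1.4), 9), -no_dist, -no_dist),
      y = 0,
      z = c(rep(0, 18), 0, 1.2)
    )
    pmhc_complex(atoms, c(C = "PEPTIDE", D = "BINDER"))
  }
  hb <- detect_hbonds(mk(2.9), "PEPTIDE", "BINDER")
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.9)
  expect_gt(hb$angle, 120)

  expect_equal(nrow(detect_hbonds(mk(5.0), "PEPTIDE", "BINDER")), 0)
})

test_that("ideal poly-Ala helix yields exactly the i -> i-4 backbone bonds", {
  n <- 12
  helix <- pmhc_complex(
    make_ideal_helix(n, residue_name = "ALA", chain_id = "C"),
    c(C = "PEPTIDE")
  )
  hb <- detect_hbonds(helix, "PEPTIDE", "PEPTIDE")
  expect_equal(nrow(hb), n - 4)
  expect_equal(hb$donor_residue - hb$acceptor_residue, rep(4L, n - 4))
  expect_true(all(hb$donor_atom == "N" & hb$acceptor_atom == "O"))
})

test_that("isolated-atom SASA matches the closed-form sphere", {
  one <- tibble::tibble(element = "C", x = 0, y = 0, z = 0)
  # custom radius via the radii table
  s <- shrake_rupley_sasa(one, probe_radius = 1.4, n_sphere_points = 960,
                          radii = c(C = 1.8))
  expect_equal(s, 4 * pi * 3.2^2, tolerance = 0.02)

  # two identical atoms far apart: each the free-atom value
  two <- tibble::tibble(element = "C", x = c(0, 100), y = 0, z = 0)
  s2 <- shrake_rupley_sasa(two, n_sphere_points = 240)
  expect_equal(s2[1], s2[2])
  expect_equal(s2[1], 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-9)

  expect_error(shrake_rupley_sasa(one, n_sphere_points = 30), ">= 60")
  expect_error(
    shrake_rupley_sasa(tibble::tibble(element = "XX", x = 0, y = 0, z = 0)),
    "radius"
  )
})

test_that("a fully caged atom has near-zero SASA; per-atom SASA never exceeds the free value", {
  # dense icosphere-like shell of carbons at 3 A around a central carbon
  shell <- fibonacci_sphere_pts <- local({
    i <- seq_len(200) - 0.5
    phi <- acos(1 - 2 * i / 200)
    th <- pi * (1 + sqrt(5)) * i
    cbind(3 * sin(phi) * cos(th), 3 * sin(phi) * sin(th), 3 * cos(phi))
  })
  atoms <- tibble::tibble(element = "C",
                          x = c(0, shell[, 1]),
                          y = c(0, shell[, 2]),
                          z = c(0, shell[, 3]))
  s <- shrake_rupley_sasa(atoms, n_sphere_points = 240)
  free <- 4 * pi * 3.1^2
  expect_lt(s[1], 0.01 * free)
  expect_true(all(s <= free + 1e-9))

  # and on a real fixture: additivity bound holds atom by atom
  cx <- toy_default()
  heavy <- cx$atoms[cx$atoms$is_heavy, ]
  sall <- shrake_rupley_sasa(heavy, n_sphere_points = 120)
  rmax <- default_vdw_radii()[heavy$element] + 1.4
  expect_true(all(sall <= 4 * pi * rmax^2 + 1e-9))
})

test_that("engagement metrics match a brute-force recomputation", {
  spec <- toy_spec()
  cx <- make_toy_pmhc(spec)
  cls <- classify_peptide_positions(cx)
  m <- engagement_metrics(cx, cls, design_id = "toy")

  orc_pep <- oracle_contact_pairs(cx, "BINDER", "PEPTIDE", 4.5)
  orc_mhc <- oracle_contact_pairs(cx, "BINDER", "MHC_HEAVY", 4.5)
  expect_equal(m$n_peptide_contacts, nrow(orc_pep))
  expect_equal(m$n_mhc_contacts, nrow(orc_mhc))
  expect_equal(m$peptide_contact_fraction,
               nrow(orc_pep) / (nrow(orc_pep) + nrow(orc_mhc)))

  # per-position sums to the total, nonzero exactly at designed contacts
  pp <- m$per_position_contacts[[1]]
  expect_equal(sum(pp), m$n_peptide_contacts)
  expect_equal(as.integer(names(pp)[pp > 0]), spec$binder_contact_positions)

  # outward coverage recomputed directly
  outward <- cls$position[cls$class == "OUTWARD"]
  expect_equal(m$outward_coverage,
               mean(outward %in% spec$binder_contact_positions))
})

test_that("binder-only-peptide contacts give fraction 1; displaced binder gives the undefined sentinel", {
  cx <- toy_default()
  m <- engagement_metrics(cx, classify_peptide_positions(cx))
  expect_equal(m$peptide_contact_fraction, 1.0)
  expect_equal(m$n_mhc_contacts, 0L)

  far <- cx
  a <- far$atoms
  a$z[a$role == "BINDER"] <- a$z[a$role == "BINDER"] + 50
  far2 <- pmhc_complex(a, far$roles)
  m2 <- engagement_metrics(far2, classify_peptide_positions(far2))
  expect_equal(m2$n_peptide_contacts + m2$n_mhc_contacts, 0L)
  expect_true(is.na(m2$peptide_contact_fraction))
})

test_that("metrics are invariant under rigid transforms", {
  cx <- toy_default()
  cls <- classify_peptide_positions(cx)
  m <- engagement_metrics(cx, cls)
  for (seed in c(3, 13)) {
    moved <- rigid_transform(cx, seed)
    mm <- engagement_metrics(moved, classify_peptide_positions(moved))
    expect_equal(mm$n_peptide_contacts, m$n_peptide_contacts)
    expect_equal(mm$n_mhc_contacts, m$n_mhc_contacts)
    expect_equal(mm$n_hbonds_to_peptide, m$n_hbonds_to_peptide)
    expect_equal(mm$outward_coverage, m$outward_coverage)
  }
})

test_that("triage passes iff all minima hold and lists every failure", {
  metrics <- tibble::tibble(
    design_id = c("a", "b", "c"),
    n_peptide_contacts = c(12L, 12L, 3L),
    n_mhc_contacts = c(5L, 5L, 40L),
    peptide_contact_fraction = c(0.7, 0.7, 0.07),
    n_hbonds_to_peptide = c(2L, 2L, 0L),
    outward_coverage = c(0.8, 0.3, 0.0),
    per_position_contacts = list(NULL, NULL, NULL)
  )
  tr <- triage_designs(metrics)
  expect_equal(tr$pass, c(TRUE, FALSE, FALSE))
  expect_equal(tr$reasons[1], "")
  expect_match(tr$reasons[2], "^outward_coverage")
  expect_equal(lengths(strsplit(tr$reasons[3], "; ")), 4L, ignore_attr = TRUE)

  # raising any threshold never grows the pass set
  base_pass <- sum(tr$pass)
  stricter <- triage_designs(metrics, min_peptide_contacts = 20)
  expect_lte(sum(stricter$pass), base_pass)

  # 100 synthetic records: pass set equals direct predicate evaluation
  set.seed(5)
  rnd <- tibble::tibble(
    design_id = sprintf("d%03d", 1:100),
    n_peptide_contacts = rpois(100, 12),
    n_mhc_contacts = rpois(100, 10),
    peptide_contact_fraction = runif(100),
    n_hbonds_to_peptide = rpois(100, 1.5),
    outward_coverage = runif(100),
    per_position_contacts = replicate(100, NULL, simplify = FALSE)
  )
  tr2 <- triage_designs(rnd)
  direct <- rnd$n_peptide_contacts >= 10 &
    rnd$peptide_contact_fraction >= 0.25 &
    rnd$outward_coverage >= 0.5 &
    rnd$n_hbonds_to_peptide >= 1
  expect_equal(tr2$pass, direct)
})
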