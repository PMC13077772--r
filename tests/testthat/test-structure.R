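test_that("PDB round trip preserves atom records and role filtering works", {
  cx <- toy_default()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pmhc_pdb(cx, path)

  roles <- c(A = "MHC_HEAVY", B = "B2M", C = "PEPTIDE", D = "BINDER")
  back <- read_pmhc(path, roles)
  expect_equal(nrow(back$atoms), nrow(cx$atoms))
  expect_equal(back$peptide_sequence, cx$peptide_sequence)
  # coordinates identical to PDB output precision (1e-3)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(cx$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(back$atoms$atom_name, cx$atoms$atom_name)

  # dropping a chain from the role map drops its atoms
  no_binder <- read_pmhc(path, roles[names(roles) != "D"])
  expect_false(any(no_binder$atoms$role == "BINDER"))
  expect_setequal(unique(no_binder$atoms$chain_id), c("A", "B", "C"))

  # role map naming an absent chain errors
  expect_error(read_pmhc(path, c(roles, Z = "OTHER")), "absent chain")
  # zero peptide chains after filtering errors
  expect_error(read_pmhc(path, c(A = "MHC_HEAVY")), "PEPTIDE")
})

test_that("alternate locations resolve to highest occupancy, ties to first", {
  # hand-written two-residue file: residue 1 CA has altloc A (0.6) / B (0.4);
  # residue 2 CA has a 0.5/0.5 tie
  lines <- c(
    "ATOM      1  N   ALA C   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA C   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA C   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      4  CA AGLY C   2       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      5  CA BGLY C   2       8.000   0.000   0.000  0.50  0.00           C",
    paste0("ATOM      6  CA  ALA C   3       3.000   0.000   0.000  1.00",
           "  0.00           C"),
    "ATOM      7  CA  ALA C   4       4.000   0.000   0.000  1.00  0.00           C",
    "ATOM      8  CA  ALA C   5       5.000   0.000   0.000  1.00  0.00           C",
    "ATOM      9  CA  ALA C   6       6.000   0.000   0.000  1.00  0.00           C",
    "ATOM     10  CA  ALA C   7       7.000   0.000   0.000  1.00  0.00           C",
    "ATOM     11  CA  ALA C   8      10.000   0.000   0.000  1.00  0.00           C",
    "END"
  )
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  cx <- read_pmhc(path, c(C = "PEPTIDE"))
  ca1 <- subset(cx$atoms, residue_index == 1 & atom_name == "CA")
  expect_equal(nrow(ca1), 1)
  expect_equal(ca1$x, 1.0)   # higher occupancy wins
  ca2 <- subset(cx$atoms, residue_index == 2 & atom_name == "CA")
  expect_equal(ca2$x, 2.0)   # tie -> first in file
})

test_that("waters, ligands and hydrogens are handled; modified residues map", {
  lines <- c(
    "ATOM      1  CA  MSE C   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA C   2       3.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ALA C   3       7.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  ALA C   4      10.500   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  ALA C   5      14.000   0.000   0.000  1.00  0.00           C",
    "ATOM      6  CA  ALA C   6      17.500   0.000   0.000  1.00  0.00           C",
    "ATOM      7  CA  ALA C   7      21.000   0.000   0.000  1.00  0.00           C",
    "ATOM      8  CA  ALA C   8      24.500   0.000   0.000  1.00  0.00           C",
    "HETATM    9  O   HOH C 101      50.000   0.000   0.000  1.00  0.00           O",
    "HETATM   10  C1  GOL C 102      60.000   0.000   0.000  1.00  0.00           C",
    "END"
  )
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  cx <- read_pmhc(path, c(C = "PEPTIDE"))
  expect_equal(nrow(cx$atoms), 8)                      # water/glycerol gone
  expect_equal(cx$atoms$residue_name[1], "MET")        # selenomethionine
  expect_equal(substr(cx$peptide_sequence, 1, 1), "M")
})

test_that("validate_complex reports the violated invariant and nothing else", {
  expect_equal(nrow(validate_complex(toy_default())), 0)

  # 7-residue peptide: length bound
  short <- toy_default(peptide = "LLFGYPVY", binder = FALSE,
                       binder_contact_positions = integer())
  a <- subset(short$atoms, !(role == "PEPTIDE" & residue_index == 8))
  v <- validate_complex(pmhc_complex(a, short$roles))
  expect_equal(v$invariant, "peptide_length_8_to_11")

  # duplicated atom key
  dup <- toy_default()
  a2 <- rbind(dup$atoms, dup$atoms[1, ])
  v2 <- validate_complex(pmhc_complex(a2, dup$roles))
  expect_true("unique_atom_key" %in% v2$invariant)
})

test_that("nonstandard residues without a known parent reject the chain", {
  cx <- toy_default()
  a <- cx$atoms
  a$residue_name[a$role == "PEPTIDE" & a$residue_index == 1] <- "XYZ"
  expect_error(pmhc_complex(a, cx$roles), "nonstandard")
})

test_that("position classification finds designed anchors and outward faces", {
  spec <- toy_spec()
  cx <- make_toy_pmhc(spec)
  cls <- classify_peptide_positions(cx)
  expect_equal(nrow(cls), nchar(spec$peptide))
  k <- nchar(spec$peptide)
  expect_equal(cls$class[cls$position %in% c(2, k)], c("ANCHOR", "ANCHOR"))
  expect_true(all(cls$class[!cls$position %in% c(2, k)] == "OUTWARD"))

  # verify the contact fractions by brute-force enumeration
  nob <- cx$atoms[cx$atoms$role != "BINDER", ]
  mhc <- as.data.frame(subset(nob, role == "MHC_HEAVY"))
  for (p in seq_len(k)) {
    res <- subset(as.data.frame(nob), role == "PEPTIDE" & residue_index == p)
    sc <- subset(res, !(atom_name %in% c("N", "CA", "C", "O", "OXT")))
    if (nrow(sc) == 0) next
    touching <- 0
    for (i in seq_len(nrow(sc))) {
      dmin <- min(sqrt((sc$x[i] - mhc$x)^2 + (sc$y[i] - mhc$y)^2 +
                         (sc$z[i] - mhc$z)^2))
      if (dmin <= 4.5) touching <- touching + 1
    }
    expect_equal(cls$sidechain_mhc_contact_fraction[cls$position == p],
                 touching / nrow(sc))
  }
})

test_that("glycine takes contact fraction 1 and far-away MHC gives 0", {
  gly <- make_toy_pmhc(toy_spec(peptide = "SGYNTVAGL", binder = FALSE,
                                binder_contact_positions = integer()))
  cls <- classify_peptide_positions(gly)
  expect_equal(cls$sidechain_mhc_contact_fraction[cls$position %in% c(2, 8)],
               c(1, 1))  # glycine convention
  expect_equal(cls$class[cls$position == 2], "ANCHOR")

  # pull the peptide far above the groove: every non-glycine fraction is 0
  far <- gly
  a <- far$atoms
  a$z[a$role == "PEPTIDE"] <- a$z[a$role == "PEPTIDE"] + 50
  far2 <- pmhc_complex(a, far$roles)
  cls2 <- classify_peptide_positions(far2)
  nongly <- cls2$residue_name != "GLY"
  expect_true(all(cls2$sidechain_mhc_contact_fraction[nongly] == 0))
  expect_true(all(cls2$sidechain_mhc_contact_fraction[!nongly] == 1))
})

test_that("classification is invariant to rigid motion and binder removal", {
  cx <- toy_default()
  cls <- classify_peptide_positions(cx)

  moved <- rigid_transform(cx, seed = 11)
  cls_moved <- classify_peptide_positions(moved)
  expect_equal(cls_moved$class, cls$class)
  expect_equal(cls_moved$sidechain_mhc_contact_fraction,
               cls$sidechain_mhc_contact_fraction, tolerance = 1e-9)
  # the SASA lattice is fixed in the lab frame, so relative SASA is only
  # rotation-invariant up to lattice discretization
  expect_equal(cls_moved$relative_sidechain_sasa,
               cls$relative_sidechain_sasa, tolerance = 0.05)

  nob <- make_toy_pmhc(toy_spec(binder = FALSE))
  cls_nob <- classify_peptide_positions(nob)
  expect_equal(cls_nob, cls)
})

test_that("classification requires an MHC heavy chain", {
  pep_only <- pmhc_complex(subset(toy_default()$atoms, role == "PEPTIDE"),
                           c(C = "PEPTIDE"))
  expect_error(classify_peptide_positions(pep_only), "MHC_HEAVY")
})
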