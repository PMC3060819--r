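# Structure reading, dihedral computation, FASTA round trips.

make_test_pdb <- function(chain, path = tempfile(fileext = ".pdb")) {
  write_pdb(chain, path)
  path
}

test_that("compute_dihedral honours the IUPAC sign convention", {
  # cis: all four points coplanar on the same side -> 0
  p <- list(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(compute_dihedral(p[[1]], p[[2]], p[[3]], p[[4]]), 0)
  # trans: opposite sides -> 180
  expect_equal(compute_dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                                c(-1, 0, 0)), 180)
  # collinear -> error
  expect_error(compute_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                c(3, 1, 0)), "collinear")
})

test_that("compute_dihedral matches an independent atan2 oracle and is
           invariant under point reversal", {
  # note: a torsion angle keeps its VALUE when the four points are
  # reversed (checked against two independent implementations); only a
  # mirror reflection flips its sign
  set.seed(11)
  for (r in 1:50) {
    p <- lapply(1:4, function(i) rnorm(3, sd = 3))
    d <- compute_dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    expect_equal(d, oracle_dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
                 tolerance = 1e-9)
    rev_d <- compute_dihedral(p[[4]], p[[3]], p[[2]], p[[1]])
    expect_equal(angle_diff(d, rev_d), 0, tolerance = 1e-9)
    # mirror reflection (z -> -z) flips the sign
    m <- lapply(p, function(v) v * c(1, 1, -1))
    expect_equal(compute_dihedral(m[[1]], m[[2]], m[[3]], m[[4]]), -d,
                 tolerance = 1e-9)
  }
})

test_that("read_structure defines phi/psi only away from termini", {
  ch <- build_backbone("mmmmm")
  ch$residues <- ch$residues[1:4, ]
  for (a in c("N", "CA", "C", "O")) ch[[a]] <- ch[[a]][1:4, ]
  ch <- backbone_chain("A", ch$residues, ch$N, ch$CA, ch$C, ch$O)
  path <- make_test_pdb(ch)
  got <- read_structure(path, chain = "A")
  expect_equal(n_residues(got), 4)
  expect_true(is.na(got$phi[1]) && all(is.finite(got$phi[2:4])))
  expect_true(is.na(got$psi[4]) && all(is.finite(got$psi[1:3])))
})

test_that("a 10 A C-N gap flags a chain break and kills the flanking
           dihedrals", {
  ch <- build_backbone("mmmmmmmmmm")
  # translate residues 6..10 away
  for (a in c("N", "CA", "C", "O")) {
    ch[[a]][6:10, ] <- ch[[a]][6:10, ] +
      matrix(c(10, 0, 0), 5, 3, byrow = TRUE)
  }
  got <- read_structure(make_test_pdb(
    backbone_chain("A", ch$residues, ch$N, ch$CA, ch$C, ch$O)), "A")
  expect_true(got$chain_break_before[6])
  expect_true(is.na(got$phi[6]))
  expect_true(is.na(got$psi[5]))
})

test_that("residues lacking backbone atoms are dropped with a warning", {
  ch <- build_backbone("mmmmmm")
  path <- tempfile(fileext = ".pdb")
  write_pdb(ch, path)
  lines <- readLines(path)
  # remove N and C of residue 3, leaving only CA/O
  drop <- grepl("^ATOM", lines) &
    substr(lines, 23, 26) == "   3" &
    trimws(substr(lines, 13, 16)) %in% c("N", "C")
  writeLines(lines[!drop], path)
  expect_warning(got <- read_structure(path, "A"), "dropped")
  expect_equal(n_residues(got), 5)
  expect_false("3" %in% got$residues$seq_label)
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.40  0.00",
    "ATOM      3  CA BALA A   1       9.999   9.999   9.999  0.60  0.00",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00  0.00",
    "END"), path)
  got <- read_structure(path, "A")
  expect_equal(got$CA[1, ], c(9.999, 9.999, 9.999))
})

test_that("PDB round trip preserves coordinates to fixed-width
           precision", {
  set.seed(5)
  ch <- build_backbone(random_pb_string(20))
  got <- read_structure(make_test_pdb(ch), "A")
  expect_lt(max(abs(got$CA - ch$CA)), 1e-3)
  expect_lt(max(abs(got$N - ch$N)), 1e-3)
  # dihedrals reproduce within PDB precision
  expect_lt(max(angle_diff(got$phi[-1], ch$phi[-1])), 0.5)
})

test_that("mmCIF reading agrees with PDB reading", {
  ch <- build_backbone("mmmddddmmm")
  cif <- tempfile(fileext = ".cif")
  rows <- character(0)
  k <- 0
  for (i in seq_len(n_residues(ch))) for (a in c("N", "CA", "C", "O")) {
    k <- k + 1
    rows <- c(rows, sprintf(
      "ATOM %d %s . ALA A %d ? %.3f %.3f %.3f 1.00 1",
      k, a, i, ch[[a]][i, 1], ch[[a]][i, 2], ch[[a]][i, 3]))
  }
  writeLines(c("data_synthetic", "loop_",
               paste0("_atom_site.", c(
                 "group_PDB", "id", "label_atom_id", "label_alt_id",
                 "label_comp_id", "auth_asym_id", "auth_seq_id",
                 "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                 "occupancy", "pdbx_PDB_model_num")),
               rows, "#"), cif)
  got <- read_structure(cif, "A")
  expect_equal(n_residues(got), 10)
  expect_equal(got$CA, ch$CA, tolerance = 1e-3, ignore_attr = TRUE)
  expect_error(read_structure(cif, "X"), "chain not found")
})

test_that("write_pb_fasta writes Z-padded strings and round-trips", {
  ch <- build_backbone("mmmmm")
  pb <- assign_pbs(ch)
  expect_equal(pb$symbols, "ZZmZZ")
  path <- tempfile(fileext = ".fasta")
  write_pb_fasta(list(pb), path)
  back <- read_fasta(path)
  expect_equal(unname(back[1]), "ZZmZZ")
  # empty list -> empty file
  p2 <- tempfile()
  write_pb_fasta(list(), p2)
  expect_equal(length(readLines(p2)), 0)
})
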