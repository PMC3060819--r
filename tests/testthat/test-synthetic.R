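# Backbone construction from PB strings and fixture generation.

test_that("built backbones have trans-peptide CA-CA spacing", {
  set.seed(83)
  ch <- build_backbone(random_pb_string(20))
  d <- sqrt(rowSums((ch$CA[-1, ] - ch$CA[-20, ])^2))
  expect_true(all(abs(d - 3.8) < 0.1))
  expect_false(any(ch$chain_break_before))
})

test_that("built dihedrals equal the prototype centres exactly", {
  al <- pb_alphabet()
  set.seed(89)
  s <- random_pb_string(15, compatible = FALSE)
  ch <- build_backbone(s)
  sym <- strsplit(s, "")[[1]]
  for (i in 2:14) {
    expect_equal(ch$phi[i], al$prototypes[sym[i], 4], tolerance = 1e-6)
    expect_equal(ch$psi[i], al$prototypes[sym[i], 5], tolerance = 1e-6)
  }
})

test_that("Z or short strings are rejected", {
  expect_error(build_backbone("mmZmm"), "undefined")
  expect_error(build_backbone("mmm"))
})

test_that("geometric assignment equals the analytic prediction on
           arbitrary strings", {
  set.seed(97)
  for (r in 1:20) {
    s <- random_pb_string(25, compatible = FALSE)
    expect_identical(assign_pbs(build_backbone(s))$symbols,
                     pb_predict_assignment(s), label = s)
  }
})

test_that("transition-compatible strings round-trip exactly", {
  set.seed(101)
  for (r in 1:20) {
    s <- random_pb_string(30)
    got <- assign_pbs(build_backbone(s))$symbols
    expect_identical(substr(got, 3, 28), substr(s, 3, 28), label = s)
  }
})

test_that("perturb_rigid: identity leaves the chain unchanged, motion
           preserves internal PBs", {
  set.seed(103)
  s <- paste0(strrep("d", 10), "klmmmmmmno", strrep("d", 10))
  ch <- build_backbone(s)
  same <- perturb_rigid(ch, 11:20)
  expect_equal(same$CA, ch$CA, tolerance = 1e-12)
  moved <- suppressWarnings(
    perturb_rigid(ch, 11:20, translation = c(0, 6, 0)))
  # interior of the moved segment keeps its PBs (dihedrals unchanged)
  pb0 <- assign_pbs(ch)$symbols
  pb1 <- assign_pbs(moved)$symbols
  expect_equal(substr(pb1, 14, 17), substr(pb0, 14, 17))
  # deviations inside the moved range exceed the displacement threshold
  aln <- residue_pair_alignment(1:30, 1:30)
  fit <- trimmed_fit(aln, ch, moved)
  dev <- column_deviations(aln, ch, moved, fit$transform)
  expect_true(all(dev[14:17] > 3))
  expect_true(all(dev[1:8] < 0.5))
})

test_that("rotation about a distant axis grows deviations with the
           lever arm", {
  s <- strrep("d", 20)
  ch <- build_backbone(s)
  rot <- perturb_rigid(ch, 1:20, rotation_deg = 180,
                       translation = c(0, 0, 0), axis = c(0, 0, 1))
  dev <- sqrt(rowSums((rot$CA - ch$CA)^2))
  dist_to_axis <- sqrt(rowSums(
    sweep(ch$CA[, 1:2], 2, colMeans(ch$CA)[1:2])^2))
  expect_gt(cor(dev, dist_to_axis), 0.99)
})

test_that("perturb_conformation splices strings of any length", {
  expect_equal(perturb_conformation("aammmmbb", 3:6, "dddd"), "aaddddbb")
  expect_equal(perturb_conformation("aammmmbb", 3:6, "mmmm"), "aammmmbb")
  expect_equal(nchar(perturb_conformation("aammmmbb", 3:6, "dddddd")), 10)
})

test_that("fixtures re-read from disk to within PDB precision", {
  fx <- suppressWarnings(make_pair_fixture("displaced", seed = 5))
  ch1 <- read_structure(fx$pdb1)
  expect_equal(n_residues(ch1), n_residues(fx$chain1))
  ok <- is.finite(fx$chain1$phi) & is.finite(ch1$phi)
  expect_lt(max(angle_diff(ch1$phi[ok], fx$chain1$phi[ok])), 0.5)
  truth <- utils::read.delim(fx$truth_file)
  expect_equal(truth$kind, "displaced")
  expect_equal(truth$expected_classification, "similar")
  aln <- read_alignment(fx$alignment, ch1, read_structure(fx$pdb2))
  expect_s3_class(aln, "ResiduePairAlignment")
})

test_that("indel fixtures force gap columns in the refined alignment", {
  fx <- suppressWarnings(make_pair_fixture("indel", seed = 11))
  expect_equal(n_residues(fx$chain2), n_residues(fx$chain1) + 2)
  sm <- load_matrix()
  pb1 <- assign_pbs(fx$chain1)
  pb2 <- assign_pbs(fx$chain2)
  lo <- fx$truth$svr_res_lo; hi <- fx$truth$svr_res_hi
  al <- pb_align(substr(pb1$symbols, lo, hi),
                 substr(pb2$symbols, lo, hi + 2), sm)
  expect_equal(sum(al$columns$s1 == "-"), 2)
})
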