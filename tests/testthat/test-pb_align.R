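# Substitution matrix handling and the Gotoh aligner.

test_that("load_matrix scales to [0,10] and round-trips", {
  sm <- toy_matrix()       # diag 5, off -1
  expect_equal(unname(diag(sm$scaled)), rep(10, 16))
  expect_equal(sm$scaled["a", "b"], 0)
  path <- tempfile(fileext = ".tsv")
  write_matrix(sm, path)
  back <- load_matrix(path)
  expect_equal(back$raw, sm$raw, tolerance = 1e-12)
  # constant matrix is degenerate
  expect_error(substitution_matrix(matrix(
    1, 16, 16, dimnames = list(letters[1:16], letters[1:16]))),
    "degenerate")
})

test_that("the packaged stand-in matrix is symmetric with positive
           diagonal dominance over helix-strand pairs", {
  sm <- load_matrix()
  expect_true(isSymmetric(unname(sm$raw)))
  expect_true(all(diag(sm$raw) > 0))
  expect_lt(sm$raw["m", "d"], -3)   # helix vs strand strongly penalised
})

test_that("asymmetric matrices are symmetrised with a warning", {
  m <- toy_matrix()$raw
  m["a", "b"] <- 2; m["b", "a"] <- 0
  path <- tempfile(fileext = ".tsv")
  utils::write.table(format(m, trim = TRUE), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  expect_warning(sm <- load_matrix(path), "symmetris")
  expect_equal(sm$raw["a", "b"], 1)
})

test_that("self-alignment and forced-gap scores are exact", {
  sm <- toy_matrix()
  al <- pb_align("klmmp", "klmmp", sm)
  expect_equal(nrow(al$columns), 5)
  expect_true(all(al$columns$s1 == al$columns$s2))
  expect_equal(al$dp_score, 5 * 10)
  # one side empty: forced all-gap, open + 2 extends
  p <- align_params()
  al2 <- pb_align("mmm", "", sm)
  expect_equal(paste(al2$columns$s2, collapse = ""), "---")
  expect_equal(al2$dp_score, -(p$gap_open + 2 * p$gap_extend))
  # both empty
  al3 <- pb_align("", "", sm)
  expect_equal(nrow(al3$columns), 0)
  expect_equal(al3$dp_score, 0)
})

test_that("projecting out gaps recovers the inputs exactly", {
  set.seed(53)
  sm <- load_matrix()
  for (r in 1:25) {
    s1 <- random_pb_string(sample(5:12, 1), compatible = FALSE)
    s2 <- random_pb_string(sample(5:12, 1), compatible = FALSE)
    al <- pb_align(s1, s2, sm)
    expect_false(any(al$columns$s1 == "-" & al$columns$s2 == "-"))
    expect_equal(paste(al$columns$s1[al$columns$s1 != "-"],
                       collapse = ""), s1)
    expect_equal(paste(al$columns$s2[al$columns$s2 != "-"],
                       collapse = ""), s2)
  }
})

test_that("dp_score equals exhaustive enumeration on short strings", {
  set.seed(59)
  sm <- load_matrix()
  for (r in 1:40) {
    n1 <- sample(0:5, 1); n2 <- sample(0:5, 1)
    s1 <- if (n1) paste(sample(c(letters[1:16], "Z"), n1, TRUE),
                        collapse = "") else ""
    s2 <- if (n2) paste(sample(c(letters[1:16], "Z"), n2, TRUE),
                        collapse = "") else ""
    expect_equal(pb_align(s1, s2, sm)$dp_score,
                 oracle_align_score(s1, s2, sm), tolerance = 1e-9,
                 label = paste(s1, "/", s2))
  }
})

test_that("free end gaps match the free-end enumeration oracle", {
  set.seed(61)
  sm <- load_matrix()
  p <- align_params(end_gaps_penalized = FALSE)
  for (r in 1:15) {
    s1 <- paste(sample(letters[1:16], sample(1:5, 1), TRUE), collapse = "")
    s2 <- paste(sample(letters[1:16], sample(1:5, 1), TRUE), collapse = "")
    expect_equal(pb_align(s1, s2, sm, p)$dp_score,
                 oracle_align_score_free_ends(s1, s2, sm),
                 tolerance = 1e-9, label = paste(s1, "/", s2))
  }
})

test_that("alignment score is symmetric in its arguments", {
  set.seed(67)
  sm <- load_matrix()
  for (r in 1:20) {
    s1 <- random_pb_string(sample(5:10, 1), compatible = FALSE)
    s2 <- random_pb_string(sample(5:10, 1), compatible = FALSE)
    expect_equal(pb_align(s1, s2, sm)$dp_score,
                 pb_align(s2, s1, sm)$dp_score, tolerance = 1e-9)
  }
})

test_that("Z scores zero against everything in the DP", {
  sm <- load_matrix()
  al <- pb_align("ZZZ", "mmm", sm)
  expect_equal(al$dp_score, 0)
  expect_equal(nrow(al$columns), 3)
})

test_that("appending a symbol moves the optimum by a bounded amount", {
  set.seed(71)
  sm <- load_matrix()
  p <- align_params()
  bound <- max(abs(sm$scaled)) + p$gap_open + p$gap_extend
  for (r in 1:20) {
    s1 <- random_pb_string(sample(5:9, 1), compatible = FALSE)
    s2 <- random_pb_string(sample(5:9, 1), compatible = FALSE)
    base <- pb_align(s1, s2, sm)$dp_score
    ext <- pb_align(paste0(s1, sample(letters[1:16], 1)), s2, sm)$dp_score
    expect_lte(abs(ext - base), bound + 1e-9)
  }
})
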