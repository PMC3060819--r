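# SCR/SVR segmentation and SVR filtering.

test_that("basic segmentation examples", {
  aln <- residue_pair_alignment(1:5, 1:5)
  seg <- segment(aln, rep(1, 5))
  expect_equal(seg$scr, data.frame(start = 0, end = 5))
  expect_length(seg$svr, 0)

  # a sub-cutoff run of length 2 is absorbed into the SVR
  aln6 <- residue_pair_alignment(1:6, 1:6)
  seg6 <- segment(aln6, c(1, 1, 4, 1, 1, 1))
  expect_equal(seg6$scr, data.frame(start = 3, end = 6))
  expect_length(seg6$svr, 1)
  expect_equal(unname(seg6$svr[[1]]$column_range), c(0, 3))
  expect_true(seg6$svr[[1]]$terminal)
})

test_that("gap columns always belong to SVRs and flag terminal", {
  aln <- residue_pair_alignment(c(NA, 1:5), c(1, 2:6))
  seg <- segment(aln, c(NA, rep(1, 5)))
  expect_equal(seg$scr, data.frame(start = 1, end = 6))
  expect_true(seg$svr[[1]]$terminal)
  expect_equal(unname(seg$svr[[1]]$column_range), c(0, 1))
})

test_that("segmentation agrees with the rule-literal oracle on random
           deviation vectors", {
  set.seed(41)
  for (r in 1:100) {
    n <- sample(5:40, 1)
    dev <- runif(n, 0, 6)
    gap <- runif(n) < 0.15
    dev[gap] <- NA
    i1 <- seq_len(n); i1[gap & seq_len(n) %% 2 == 0] <- NA
    i2 <- seq_len(n); i2[gap & seq_len(n) %% 2 == 1] <- NA
    aln <- residue_pair_alignment(i1, i2)
    seg <- segment(aln, dev)
    want <- oracle_segment(!gap, dev)
    got <- rep(FALSE, n)
    for (k in seq_len(nrow(seg$scr))) {
      got[(seg$scr$start[k] + 1):seg$scr$end[k]] <- TRUE
    }
    expect_identical(got, want)
    # tiling: SCRs and SVRs partition the columns
    cover <- got
    for (s in seg$svr) {
      rng <- (s$column_range["start"] + 1):s$column_range["end"]
      expect_false(any(cover[rng]))
      cover[rng] <- TRUE
    }
    expect_true(all(cover))
  }
})

test_that("raising the cutoff never shrinks total SCR coverage", {
  set.seed(43)
  n <- 60
  dev <- runif(n, 0, 8)
  aln <- residue_pair_alignment(1:n, 1:n)
  cov <- function(cut) {
    seg <- segment(aln, dev, segmentation_params(deviation_cutoff = cut))
    sum(seg$scr$end - seg$scr$start)
  }
  cuts <- c(1, 2, 3, 4, 6, 8)
  expect_true(all(diff(vapply(cuts, cov, 0)) >= 0))
})

test_that("extract_svr_pb projects the PB substrings", {
  ch1 <- build_backbone("dddddklmmmkldddddd")
  ch2 <- build_backbone("dddddklmmkldddddd")
  pb1 <- assign_pbs(ch1); pb2 <- assign_pbs(ch2)
  # alignment: 1:1 until residue 9, then chain1 residue 10 gapped
  i1 <- 1:18
  i2 <- c(1:9, NA, 10:17)
  aln <- residue_pair_alignment(i1, i2)
  sv <- pbrefine:::svr_segment(5, 12, 18)   # columns 6..12 (half-open)
  sv <- extract_svr_pb(sv, aln, pb1, pb2)
  s1 <- strsplit(pb1$symbols, "")[[1]]
  s2 <- strsplit(pb2$symbols, "")[[1]]
  expect_equal(sv$pb_sub_1, paste(s1[6:12], collapse = ""))
  expect_equal(sv$pb_sub_2, paste(s2[c(6:9, 10:11)], collapse = ""))
  # projection length equals non-gap count in range per row
  expect_equal(nchar(sv$pb_sub_1), sum(!is.na(i1[6:12])))
  expect_equal(nchar(sv$pb_sub_2), sum(!is.na(i2[6:12])))
  expect_false(sv$unalignable)
})

test_that("an SVR with one empty side is unalignable", {
  ch1 <- build_backbone("ddddddd")
  ch2 <- build_backbone("ddddd")
  aln <- residue_pair_alignment(c(1:5, 6, 7), c(1:5, NA, NA))
  pb1 <- assign_pbs(ch1); pb2 <- assign_pbs(ch2)
  sv <- pbrefine:::svr_segment(5, 7, 7)
  sv <- extract_svr_pb(sv, aln, pb1, pb2)
  expect_true(sv$unalignable)
  expect_equal(sv$pb_sub_2, "")
})

test_that("filter_complete applies the strictly-more-than rule and the
           terminal exclusion", {
  mk <- function(npairs, terminal) {
    sv <- pbrefine:::svr_segment(if (terminal) 0 else 2, 10, 20)
    sv$before_alignment <- pb_alignment(rep("m", npairs),
                                        rep("m", npairs))
    sv
  }
  svrs <- list(mk(3, FALSE), mk(4, FALSE), mk(10, TRUE))
  kept <- filter_complete(svrs)
  expect_length(kept, 2)    # 3 pairs is not "more than three"
  expect_equal(vapply(kept, function(s) {
    n_aligned_pb_pairs(s$before_alignment)
  }, 0L), c(4L, 10L))
  kept_sdm <- filter_complete(svrs, for_sdm = TRUE)
  expect_length(kept_sdm, 1)  # terminal SVR additionally removed
  # Z pairs do not count as aligned PB pairs
  svz <- mk(5, FALSE)
  svz$before_alignment <- pb_alignment(c("m", "m", "Z", "m", "m"),
                                       c("m", "Z", "m", "m", "-"))
  expect_equal(n_aligned_pb_pairs(svz$before_alignment), 2L)
})
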