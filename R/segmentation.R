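# SCR/SVR segmentation of a superposed pairwise alignment.
#
# The rule: a Structurally Conserved Region (SCR) is a maximal run of at
# least `min_scr_length` consecutive non-gap columns whose CA-CA deviation
# is each below `deviation_cutoff` under the current superposition.  Every
# other column belongs to exactly one maximal Structurally Variable Region
# (SVR); gap columns are always SVR members.

#' Segmentation parameters
#'
#' @param deviation_cutoff CA-CA deviation (Angstrom) below which a column
#'   can belong to an SCR.  Default 3.0.
#' @param min_scr_length minimum SCR run length in columns.  Default 3.
#' @param min_svr_aligned_pbs an SVR is "complete" when its initial
#'   alignment has strictly more than this many aligned PB pairs.
#'   Default 3.
#' @return object of class `SegmentationParams`.
#' @export
segmentation_params <- function(deviation_cutoff = 3.0, min_scr_length = 3,
                                min_svr_aligned_pbs = 3) {
  stopifnot(deviation_cutoff > 0, min_scr_length > 0,
            min_svr_aligned_pbs > 0)
  structure(list(deviation_cutoff = deviation_cutoff,
                 min_scr_length = min_scr_length,
                 min_svr_aligned_pbs = min_svr_aligned_pbs),
            class = "SegmentationParams")
}

#' Residue-pair alignment
#'
#' Columns of (residue index or gap, residue index or gap) into two
#' `BackboneChain`s.  Indices must be strictly increasing per chain and no
#' column may be gap/gap.
#'
#' @param i1,i2 integer vectors with `NA` for gaps, equal length.
#' @param source free-text provenance label.
#' @return object of class `ResiduePairAlignment`.
#' @export
residue_pair_alignment <- function(i1, i2, source = "constructed") {
  stopifnot(length(i1) == length(i2))
  if (any(is.na(i1) & is.na(i2))) stop("gap/gap column not allowed")
  for (v in list(i1, i2)) {
    vv <- v[!is.na(v)]
    if (length(vv) > 1 && any(diff(vv) <= 0)) {
      stop("residue indices must be strictly increasing")
    }
  }
  structure(list(columns = data.frame(i1 = as.integer(i1),
                                      i2 = as.integer(i2)),
                 source = source),
            class = "ResiduePairAlignment")
}

#' Build a residue-pair alignment from an aligned FASTA pair
#'
#' The two gapped records must, once gaps are removed, reproduce the
#' amino acid sequences of the two chains (mismatches warn; length
#' mismatch is an error).
#'
#' @param path aligned FASTA with exactly two records (`-` gaps).
#' @param chain1,chain2 the corresponding `BackboneChain`s.
#' @return a [residue_pair_alignment()].
#' @export
read_alignment <- function(path, chain1, chain2) {
  seqs <- read_fasta(path)
  if (length(seqs) != 2) stop("alignment FASTA must have exactly 2 records")
  g1 <- strsplit(seqs[[1]], "")[[1]]
  g2 <- strsplit(seqs[[2]], "")[[1]]
  if (length(g1) != length(g2)) stop("aligned records differ in length")
  for (k in 1:2) {
    ung <- gsub("-", "", seqs[[k]])
    ch <- if (k == 1) chain1 else chain2
    if (nchar(ung) != n_residues(ch)) {
      stop(sprintf("record %d has %d residues but chain %s has %d",
                   k, nchar(ung), ch$chain_id, n_residues(ch)))
    }
    if (toupper(ung) != toupper(chain_sequence(ch))) {
      warning("record ", k, " sequence differs from chain ",
              ch$chain_id, " sequence")
    }
  }
  i1 <- ifelse(g1 == "-", NA_integer_, cumsum(g1 != "-"))
  i2 <- ifelse(g2 == "-", NA_integer_, cumsum(g2 != "-"))
  keep <- !(is.na(i1) & is.na(i2))
  residue_pair_alignment(i1[keep], i2[keep],
                         source = paste("FASTA", basename(path)))
}

#' Segment an alignment into SCRs and SVRs
#'
#' @param alignment a [residue_pair_alignment()].
#' @param deviations per-column CA-CA deviations ([column_deviations()]);
#'   `NA` (gap / missing CA) columns can never be SCR members.
#' @param params a [segmentation_params()].
#' @return list with `scr`: data.frame of half-open 0-based column ranges
#'   `[start, end)`; and `svr`: list of `SVRSegment`s (fields
#'   `column_range`, `terminal`).
#' @export
segment <- function(alignment, deviations, params = segmentation_params()) {
  n <- nrow(alignment$columns)
  if (n == 0) return(list(scr = data.frame(start = integer(0),
                                           end = integer(0)),
                          svr = list()))
  stopifnot(length(deviations) == n)
  ok <- !is.na(deviations) & deviations < params$deviation_cutoff &
    !is.na(alignment$columns$i1) & !is.na(alignment$columns$i2)
  # maximal runs of ok-columns of length >= min_scr_length are SCRs
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  is_scr <- rep(FALSE, n)
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= params$min_scr_length) {
      is_scr[starts[k]:ends[k]] <- TRUE
    }
  }
  scr <- run_ranges(is_scr)
  svr_ranges <- run_ranges(!is_scr)
  svr <- lapply(seq_len(nrow(svr_ranges)), function(k) {
    svr_segment(svr_ranges$start[k], svr_ranges$end[k], n)
  })
  list(scr = scr, svr = svr)
}

run_ranges <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])  # 0-based
}

svr_segment <- function(start, end, n_columns) {
  structure(list(column_range = c(start = start, end = end),
                 terminal = (start == 0 || end == n_columns),
                 pb_sub_1 = NULL, pb_sub_2 = NULL,
                 before_alignment = NULL, after_alignment = NULL),
            class = "SVRSegment")
}

#' Project PB strings into an SVR
#'
#' Concatenates the PB symbols of each chain's residues inside the SVR's
#' column range, dropping gaps.  `Z` symbols are retained.
#'
#' @param svr an `SVRSegment`.
#' @param alignment the [residue_pair_alignment()] the SVR ranges over.
#' @param pb1,pb2 [pb_sequence()]s of the two chains.
#' @return the SVR with `pb_sub_1`, `pb_sub_2` (strings) and
#'   `residue_idx_1`, `residue_idx_2` (chain residue indices) filled in;
#'   `unalignable` is set when either side contributes no residues.
#' @export
extract_svr_pb <- function(svr, alignment, pb1, pb2) {
  rng <- (svr$column_range["start"] + 1):svr$column_range["end"]
  i1 <- alignment$columns$i1[rng]; i1 <- i1[!is.na(i1)]
  i2 <- alignment$columns$i2[rng]; i2 <- i2[!is.na(i2)]
  s1 <- strsplit(pb1$symbols, "")[[1]]
  s2 <- strsplit(pb2$symbols, "")[[1]]
  svr$pb_sub_1 <- paste(s1[i1], collapse = "")
  svr$pb_sub_2 <- paste(s2[i2], collapse = "")
  svr$residue_idx_1 <- i1
  svr$residue_idx_2 <- i2
  svr$unalignable <- length(i1) == 0 || length(i2) == 0
  svr
}

#' Count aligned PB pairs in a PB-level alignment
#'
#' A column counts when both symbols are defined PBs (not gaps, not `Z`).
#'
#' @param pb_aln a [pb_alignment()].
#' @return integer count.
#' @export
n_aligned_pb_pairs <- function(pb_aln) {
  sum(pb_aln$columns$s1 %in% PB_LABELS & pb_aln$columns$s2 %in% PB_LABELS)
}

#' Filter SVRs to "complete" ones
#'
#' Keeps SVRs whose initial (before) PB alignment has strictly more than
#' `min_svr_aligned_pbs` aligned PB pairs.  With `for_sdm = TRUE`,
#' terminal SVRs (touching either end of the alignment) are also removed,
#' matching the rule used for superposition-based (SDM) analysis.
#'
#' @param svrs list of `SVRSegment`s with `before_alignment` filled in.
#' @param params a [segmentation_params()].
#' @param for_sdm drop terminal SVRs as well.
#' @return filtered list.
#' @export
filter_complete <- function(svrs, params = segmentation_params(),
                            for_sdm = FALSE) {
  keep <- vapply(svrs, function(s) {
    if (is.null(s$before_alignment)) return(FALSE)
    if (for_sdm && s$terminal) return(FALSE)
    n_aligned_pb_pairs(s$before_alignment) > params$min_svr_aligned_pbs
  }, TRUE)
  svrs[keep]
}
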