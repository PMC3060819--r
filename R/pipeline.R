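# End-to-end refinement of one structure pair:
#   assign PBs -> global fit -> per-column deviations -> SCR/SVR
#   segmentation -> per-SVR PB re-alignment -> scores, classification,
#   SDM -> report.
# SCR equivalences pass through untouched; only SVRs are re-aligned.

#' Refine the structurally variable regions of a structure pair
#'
#' @param chain1,chain2 `BackboneChain`s.
#' @param alignment initial [residue_pair_alignment()] (e.g. from
#'   [read_alignment()]); its equivalences are the "before" baseline.
#' @param sm a `SubstitutionMatrix` (default: packaged stand-in).
#' @param seg_params a [segmentation_params()].
#' @param align_par an [align_params()].
#' @param score_par a [score_params()].
#' @param sdm_par an [sdm_params()].
#' @param pair_id label used in reports.
#' @return object of class `RefinementReport`: global fit and RMSD over
#'   SCR columns, the segment table, one record per SVR (before/after
#'   alignments, `SVRScores`, deltas), refined residue equivalences and
#'   the 16x16 PB substitution-difference matrix.
#' @export
refine_pair <- function(chain1, chain2, alignment, sm = load_matrix(),
                        seg_params = segmentation_params(),
                        align_par = align_params(),
                        score_par = score_params(),
                        sdm_par = sdm_params(),
                        pair_id = paste(chain1$chain_id, chain2$chain_id,
                                        sep = "_")) {
  pb1 <- assign_pbs(chain1)
  pb2 <- assign_pbs(chain2)
  # trimmed global fit, then refreshed on SCR columns
  fit <- trimmed_fit(alignment, chain1, chain2,
                     cutoff = seg_params$deviation_cutoff)
  dev <- column_deviations(alignment, chain1, chain2, fit$transform)
  seg0 <- segment(alignment, dev, seg_params)
  scr_cols <- ranges_to_columns(seg0$scr)
  if (length(scr_cols) >= 3) {
    fit <- fit_on_columns(alignment, chain1, chain2, scr_cols)
    dev <- column_deviations(alignment, chain1, chain2, fit$transform)
    seg0 <- segment(alignment, dev, seg_params)
    scr_cols <- ranges_to_columns(seg0$scr)
  }
  global_rmsd_scr <- if (length(scr_cols)) {
    sqrt(mean(dev[scr_cols]^2, na.rm = TRUE))
  } else NA_real_

  svrs <- lapply(seg0$svr, function(sv) {
    sv <- extract_svr_pb(sv, alignment, pb1, pb2)
    sv$before_alignment <- project_before(sv, alignment, pb1, pb2)
    sv
  })

  records <- lapply(svrs, function(sv) {
    refine_svr(sv, alignment, chain1, chain2, sm, seg_params, align_par,
               score_par, sdm_par)
  })

  equivalences <- refined_equivalences(seg0, records, alignment)
  subdiff <- substitution_difference(
    lapply(records, function(r) r$before_alignment),
    lapply(records, function(r) r$after_alignment))

  structure(list(pair_id = pair_id, chain1 = chain1, chain2 = chain2,
                 pb1 = pb1, pb2 = pb2,
                 transform = fit$transform,
                 global_rmsd_scr = global_rmsd_scr,
                 deviations = dev, scr = seg0$scr, svr = records,
                 equivalences = equivalences,
                 substitution_difference = subdiff,
                 matrix_name = sm$name,
                 .aln = alignment),
            class = "RefinementReport")
}

ranges_to_columns <- function(ranges) {
  if (nrow(ranges) == 0) return(integer(0))
  unlist(lapply(seq_len(nrow(ranges)), function(k) {
    (ranges$start[k] + 1):ranges$end[k]
  }))
}

# "before" PB alignment: projection of the input residue alignment into
# PB space over the SVR's columns
project_before <- function(sv, alignment, pb1, pb2) {
  rng <- (sv$column_range["start"] + 1):sv$column_range["end"]
  s1 <- strsplit(pb1$symbols, "")[[1]]
  s2 <- strsplit(pb2$symbols, "")[[1]]
  i1 <- alignment$columns$i1[rng]
  i2 <- alignment$columns$i2[rng]
  pb_alignment(ifelse(is.na(i1), "-", s1[i1]),
               ifelse(is.na(i2), "-", s2[i2]))
}

refine_svr <- function(sv, alignment, chain1, chain2, sm, seg_params,
                       align_par, score_par, sdm_par) {
  rng <- (sv$column_range["start"] + 1):sv$column_range["end"]
  rec <- list(column_range = sv$column_range, terminal = sv$terminal,
              pb_sub_1 = sv$pb_sub_1, pb_sub_2 = sv$pb_sub_2,
              .idx1 = sv$residue_idx_1, .idx2 = sv$residue_idx_2,
              before_alignment = sv$before_alignment,
              after_alignment = NULL, unrefined = FALSE,
              complete = n_aligned_pb_pairs(sv$before_alignment) >
                seg_params$min_svr_aligned_pbs)
  if (sv$unalignable) {
    rec$unrefined <- TRUE
    rec$reason <- "one side contributes no residues"
    return(rec)
  }
  aft <- try(pb_align(sv$pb_sub_1, sv$pb_sub_2, sm, align_par),
             silent = TRUE)
  if (inherits(aft, "try-error")) {
    rec$unrefined <- TRUE
    rec$reason <- "PB alignment failed"
    return(rec)
  }
  rec$after_alignment <- aft
  # residue equivalences and local superpositions
  before_pairs <- stats::na.omit(alignment$columns[rng, ])
  after_pairs <- map_pb_to_residue_equivalences(
    aft, sv$residue_idx_1, sv$residue_idx_2)
  rec$equivalences_after <- after_pairs
  loc_b <- local_sdm_inputs(before_pairs, chain1, chain2,
                            nrow(sv$before_alignment$columns))
  loc_a <- local_sdm_inputs(after_pairs, chain1, chain2,
                            nrow(aft$columns))
  use_sdm <- !sv$terminal      # terminal SVRs excluded from SDM analysis
  rec$before <- score_one(sv$before_alignment, sm, score_par, sdm_par,
                          loc_b, use_sdm)
  rec$after <- score_one(aft, sm, score_par, sdm_par, loc_a, use_sdm)
  if (!is.null(rec$before) && !is.null(rec$after)) {
    rec$delta <- compare_scores(rec$before, rec$after)
    rec$classification <- rec$after$classification
  } else {
    rec$unrefined <- TRUE
    rec$reason <- "no aligned PB pairs to score"
  }
  rec
}

score_one <- function(pb_aln, sm, score_par, sdm_par, loc, use_sdm) {
  if (length(raw_pair_scores(pb_aln, sm)) == 0) return(NULL)
  svr_scores(pb_aln, sm, score_par,
             rmsd_local = if (use_sdm) loc$rmsd else NA_real_,
             n_equiv = loc$n_equiv, n_total = loc$n_total,
             sdm_par = sdm_par)
}

local_sdm_inputs <- function(pairs, chain1, chain2, n_total) {
  if (is.null(pairs) || nrow(pairs) < 3) {
    return(list(rmsd = NA_real_, n_equiv = nrow(pairs), n_total = n_total))
  }
  fit <- kabsch_fit(chain2$CA[pairs$i2, , drop = FALSE],
                    chain1$CA[pairs$i1, , drop = FALSE])
  list(rmsd = fit$rmsd, n_equiv = nrow(pairs), n_total = n_total)
}

#' Map an SVR PB alignment back to residue equivalences
#'
#' Every column of the PB alignment with both symbols present (gapless)
#' maps to the pair of central residues of the two 5-residue windows.
#'
#' @param pb_aln a [pb_alignment()] of the SVR substrings.
#' @param idx1,idx2 chain residue indices underlying the two substrings.
#' @return data.frame with columns `i1`, `i2`, strictly increasing.
#' @export
map_pb_to_residue_equivalences <- function(pb_aln, idx1, idx2) {
  k1 <- 0L; k2 <- 0L
  out1 <- integer(0); out2 <- integer(0)
  for (r in seq_len(nrow(pb_aln$columns))) {
    a <- pb_aln$columns$s1[r]; b <- pb_aln$columns$s2[r]
    if (a != "-") k1 <- k1 + 1L
    if (b != "-") k2 <- k2 + 1L
    if (a != "-" && b != "-") {
      out1 <- c(out1, idx1[k1]); out2 <- c(out2, idx2[k2])
    }
  }
  data.frame(i1 = out1, i2 = out2)
}

refined_equivalences <- function(seg0, records, alignment) {
  pieces <- list()
  for (k in seq_len(nrow(seg0$scr))) {
    rng <- (seg0$scr$start[k] + 1):seg0$scr$end[k]
    pieces[[length(pieces) + 1]] <-
      cbind(stats::na.omit(alignment$columns[rng, ]), region = "SCR")
  }
  for (r in records) {
    if (!is.null(r$equivalences_after) && nrow(r$equivalences_after)) {
      pieces[[length(pieces) + 1]] <-
        cbind(r$equivalences_after, region = "SVR")
    }
  }
  if (!length(pieces)) {
    return(data.frame(i1 = integer(0), i2 = integer(0),
                      region = character(0)))
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$i1), ]
}

#' PB substitution-difference matrix
#'
#' Counts PB-pair occurrences (unordered pairs accumulated symmetrically)
#' across a set of alignments after minus before.  Gap and `Z` columns do
#' not count.
#'
#' @param before,after lists of [pb_alignment()]s (`NULL` entries
#'   skipped).
#' @param normalize divide each row by the total count of its PB across
#'   both alignment sets (as in per-PB normalised difference maps).
#' @return 16 x 16 matrix (integer counts unless normalised).
#' @export
substitution_difference <- function(before, after, normalize = FALSE) {
  count <- function(alns) {
    m <- matrix(0L, 16, 16, dimnames = list(PB_LABELS, PB_LABELS))
    for (al in alns) {
      if (is.null(al)) next
      s1 <- al$columns$s1; s2 <- al$columns$s2
      ok <- s1 %in% PB_LABELS & s2 %in% PB_LABELS
      for (r in which(ok)) {
        m[s1[r], s2[r]] <- m[s1[r], s2[r]] + 1L
        if (s1[r] != s2[r]) m[s2[r], s1[r]] <- m[s2[r], s1[r]] + 1L
      }
    }
    m
  }
  d <- count(after) - count(before)
  if (normalize) {
    tot <- rowSums(count(after) + count(before))
    tot[tot == 0] <- 1
    d <- d / tot
  }
  d
}

#' @export
print.RefinementReport <- function(x, ...) {
  cat(sprintf("RefinementReport %s: %d SCR(s), %d SVR(s)\n",
              x$pair_id, nrow(x$scr), length(x$svr)))
  if (length(x$svr) == 0) cat("no variable regions\n")
  if (!is.na(x$global_rmsd_scr)) {
    cat(sprintf("global RMSD over SCR columns: %.3f A\n",
                x$global_rmsd_scr))
  }
  for (k in seq_along(x$svr)) {
    r <- x$svr[[k]]
    if (r$unrefined) {
      cat(sprintf("SVR %d [%d,%d): unrefined (%s)\n", k,
                  r$column_range["start"], r$column_range["end"],
                  r$reason))
      next
    }
    cat(sprintf(
      "SVR %d [%d,%d)%s: SAP %.2f -> %.2f, SDM %s -> %s, %s\n",
      k, r$column_range["start"], r$column_range["end"],
      if (r$terminal) " (terminal)" else "",
      r$before$sap, r$after$sap,
      fmt_na(r$before$sdm), fmt_na(r$after$sdm), r$classification))
  }
  invisible(x)
}

fmt_na <- function(x) if (is.na(x)) "NA" else sprintf("%.2f", x)

#' Write a RefinementReport to files
#'
#' Emits `<base>_svr.tsv` (per-SVR score table), `<base>_equiv.tsv`
#' (refined residue equivalences with author numbering),
#' `<base>_report.json` (everything, machine readable),
#' `<base>_refined_aa.fasta` and `<base>_refined_pb.fasta` (the refined
#' alignment with SCRs untouched and SVRs re-aligned).  Output is
#' deterministic: identical inputs give byte-identical files.
#'
#' @param report a `RefinementReport`.
#' @param base output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(report, base) {
  svr_tab <- svr_table(report)
  f1 <- paste0(base, "_svr.tsv")
  utils::write.table(svr_tab, f1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  eq <- report$equivalences
  eq_out <- data.frame(
    res1 = report$chain1$residues$seq_label[eq$i1],
    res2 = report$chain2$residues$seq_label[eq$i2],
    region = eq$region)
  f2 <- paste0(base, "_equiv.tsv")
  utils::write.table(eq_out, f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f3 <- paste0(base, "_report.json")
  jsonlite::write_json(report_to_list(report), f3, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  refined <- refined_alignment_strings(report)
  f4 <- paste0(base, "_refined_aa.fasta")
  write_fasta(refined$aa, f4)
  f5 <- paste0(base, "_refined_pb.fasta")
  write_fasta(refined$pb, f5)
  invisible(c(f1, f2, f3, f4, f5))
}

svr_table <- function(report) {
  rows <- lapply(seq_along(report$svr), function(k) {
    r <- report$svr[[k]]
    if (r$unrefined) {
      return(data.frame(svr = k, start = r$column_range["start"],
                        end = r$column_range["end"],
                        terminal = r$terminal, complete = r$complete,
                        n_pairs_after = NA, sap_before = NA,
                        sap_after = NA, sca_before = NA, sca_after = NA,
                        rmsd_before = NA, rmsd_after = NA,
                        sdm_before = NA, sdm_after = NA,
                        class_before = NA, class_after = NA,
                        delta_sap = NA, delta_sdm = NA,
                        delta_gap_openings = NA,
                        cell_score = NA, cell_sdm = NA))
    }
    data.frame(svr = k, start = r$column_range["start"],
               end = r$column_range["end"], terminal = r$terminal,
               complete = r$complete,
               n_pairs_after = r$after$n_aligned_pairs,
               sap_before = round(r$before$sap, 6),
               sap_after = round(r$after$sap, 6),
               sca_before = round(r$before$sca, 6),
               sca_after = round(r$after$sca, 6),
               rmsd_before = round6(r$before$rmsd_local),
               rmsd_after = round6(r$after$rmsd_local),
               sdm_before = round6(r$before$sdm),
               sdm_after = round6(r$after$sdm),
               class_before = r$before$classification,
               class_after = r$after$classification,
               delta_sap = round6(r$delta$delta_sap),
               delta_sdm = round6(r$delta$delta_sdm),
               delta_gap_openings = r$delta$delta_gap_openings,
               cell_score = r$delta$cell$score,
               cell_sdm = r$delta$cell$sdm)
  })
  if (!length(rows)) {
    return(data.frame(svr = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

round6 <- function(x) if (is.null(x) || all(is.na(x))) NA else round(x, 6)

report_to_list <- function(report) {
  list(pair_id = report$pair_id,
       matrix = report$matrix_name,
       global_rmsd_scr = report$global_rmsd_scr,
       n_scr = nrow(report$scr), n_svr = length(report$svr),
       scr = report$scr,
       svr = svr_table(report),
       substitution_difference = report$substitution_difference)
}

refined_alignment_strings <- function(report) {
  aln_cols <- list()   # list of c(i1-or-NA, i2-or-NA)
  segs <- segment_order(report)
  for (s in segs) {
    if (s$type == "SCR") {
      for (r in s$cols) {
        aln_cols[[length(aln_cols) + 1]] <- r
      }
    } else {
      rec <- report$svr[[s$idx]]
      if (is.null(rec$after_alignment)) {
        # unrefined: keep original columns
        for (r in s$cols) aln_cols[[length(aln_cols) + 1]] <- r
      } else {
        k1 <- 0L; k2 <- 0L
        idx1 <- svr_indices(report, rec, 1)
        idx2 <- svr_indices(report, rec, 2)
        for (r in seq_len(nrow(rec$after_alignment$columns))) {
          a <- rec$after_alignment$columns$s1[r]
          b <- rec$after_alignment$columns$s2[r]
          if (a != "-") k1 <- k1 + 1L
          if (b != "-") k2 <- k2 + 1L
          aln_cols[[length(aln_cols) + 1]] <-
            c(if (a != "-") idx1[k1] else NA_integer_,
              if (b != "-") idx2[k2] else NA_integer_)
        }
      }
    }
  }
  m <- do.call(rbind, aln_cols)
  aa1 <- strsplit(chain_sequence(report$chain1), "")[[1]]
  aa2 <- strsplit(chain_sequence(report$chain2), "")[[1]]
  p1 <- strsplit(report$pb1$symbols, "")[[1]]
  p2 <- strsplit(report$pb2$symbols, "")[[1]]
  ids <- c(report$chain1$chain_id, report$chain2$chain_id)
  list(aa = setNames(c(
         paste(ifelse(is.na(m[, 1]), "-", aa1[m[, 1]]), collapse = ""),
         paste(ifelse(is.na(m[, 2]), "-", aa2[m[, 2]]), collapse = "")),
         ids),
       pb = setNames(c(
         paste(ifelse(is.na(m[, 1]), "-", p1[m[, 1]]), collapse = ""),
         paste(ifelse(is.na(m[, 2]), "-", p2[m[, 2]]), collapse = "")),
         ids))
}

# interleave SCR and SVR segments in column order
segment_order <- function(report) {
  segs <- list()
  for (k in seq_len(nrow(report$scr))) {
    rng <- (report$scr$start[k] + 1):report$scr$end[k]
    segs[[length(segs) + 1]] <- list(
      type = "SCR", start = report$scr$start[k],
      cols = lapply(rng, function(r) {
        c(report_col(report, r, 1), report_col(report, r, 2))
      }))
  }
  for (k in seq_along(report$svr)) {
    rec <- report$svr[[k]]
    rng <- (rec$column_range["start"] + 1):rec$column_range["end"]
    segs[[length(segs) + 1]] <- list(
      type = "SVR", start = rec$column_range["start"], idx = k,
      cols = lapply(rng, function(r) {
        c(report_col(report, r, 1), report_col(report, r, 2))
      }))
  }
  segs[order(vapply(segs, function(s) s$start, 0))]
}

report_col <- function(report, r, side) {
  # original alignment columns are stashed on first use
  report$.aln$columns[[c("i1", "i2")[side]]][r]
}

svr_indices <- function(report, rec, side) {
  if (side == 1) rec$.idx1 else rec$.idx2
}
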