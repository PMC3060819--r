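# Similarity scores for PB-level alignments and the structural distance
# metric (SDM) for local superpositions.
#
# SAP (Score for Aligned Pairs): mean raw-matrix value over aligned PB
# pairs, gaps and Z excluded.  SCA (Score for Complete Alignment): raw
# pair values plus a fixed penalty (-3) for every gap column, divided by
# the alignment length.  Both use the RAW matrix: the published score
# ranges (a classification cutoff of -0.42, worked examples near -2)
# are negative, which is impossible on the [0, 10]-scaled matrix that
# only the DP aligner uses.

#' Scoring parameters
#'
#' @param gap_score value assigned to every gap column in SCA
#'   (default -3).
#' @param similarity_cutoff SAP value strictly above which an SVR is
#'   called conformationally similar (default -0.42).
#' @return object of class `ScoreParams`.
#' @export
score_params <- function(gap_score = -3, similarity_cutoff = -0.42) {
  stopifnot(is.finite(gap_score), is.finite(similarity_cutoff))
  structure(list(gap_score = gap_score,
                 similarity_cutoff = similarity_cutoff),
            class = "ScoreParams")
}

#' SDM parameters
#'
#' @param max_rmsd normalising constant for RMS = rmsd / max_rmsd
#'   (default 24.97, the corpus maximum used in the source analysis).
#' @param w_equiv,w_rms weights of the equivalence fraction and the RMS
#'   terms; normalised to sum to 1.
#' @return object of class `SDMParams`.
#' @export
sdm_params <- function(max_rmsd = 24.97, w_equiv = 0.5, w_rms = 0.5) {
  stopifnot(max_rmsd > 0, w_equiv > 0, w_rms > 0)
  s <- w_equiv + w_rms
  structure(list(max_rmsd = max_rmsd, w_equiv = w_equiv / s,
                 w_rms = w_rms / s),
            class = "SDMParams")
}

raw_pair_scores <- function(pb_aln, sm) {
  s1 <- pb_aln$columns$s1; s2 <- pb_aln$columns$s2
  ok <- s1 %in% PB_LABELS & s2 %in% PB_LABELS
  if (!any(ok)) return(numeric(0))
  sm$raw[cbind(s1[ok], s2[ok])]
}

#' Score for Aligned Pairs (SAP)
#'
#' Mean raw substitution value over aligned PB pairs; gap columns and
#' pairs involving `Z` are excluded.
#'
#' @param pb_aln a [pb_alignment()].
#' @param sm a `SubstitutionMatrix`.
#' @return numeric SAP; errors when no aligned PB pair exists.
#' @export
sap <- function(pb_aln, sm) {
  v <- raw_pair_scores(pb_aln, sm)
  if (length(v) == 0) stop("undefined SAP: no aligned PB pairs")
  mean(v)
}

#' Score for Complete Alignment (SCA)
#'
#' Sum of raw substitution values over aligned PB pairs plus
#' `gap_score` for every gap column, divided by the alignment length.
#' Columns pairing `Z` with a symbol contribute 0 (not a gap, no defined
#' conformation).
#'
#' @param pb_aln a [pb_alignment()].
#' @param sm a `SubstitutionMatrix`.
#' @param params a [score_params()].
#' @return numeric SCA.
#' @export
sca <- function(pb_aln, sm, params = score_params()) {
  len <- nrow(pb_aln$columns)
  if (len == 0) stop("undefined SCA: empty alignment")
  gaps <- sum(pb_aln$columns$s1 == "-" | pb_aln$columns$s2 == "-")
  (sum(raw_pair_scores(pb_aln, sm)) + params$gap_score * gaps) / len
}

#' Classify an SVR by its SAP score
#'
#' Conformationally similar iff `sap_value` is strictly above the cutoff;
#' a score exactly at the cutoff is dissimilar.
#'
#' @param sap_value numeric SAP.
#' @param params a [score_params()].
#' @return `"similar"` or `"dissimilar"`.
#' @export
classify <- function(sap_value, params = score_params()) {
  stopifnot(is.finite(sap_value))
  if (sap_value > params$similarity_cutoff) "similar" else "dissimilar"
}

#' Re-derive a similarity cutoff from SCR scores
#'
#' The published cutoff was chosen so that 90% of SCR scores lie above
#' it; with a different matrix or corpus the analogous cutoff is the
#' empirical lower `quantile` of SCR SAP scores (linear interpolation,
#' `stats::quantile` type 7).
#'
#' @param scr_saps numeric vector of SAP scores over SCRs (>= 10 values).
#' @param quantile lower tail probability (default 0.10).
#' @return numeric cutoff.
#' @export
calibrate_cutoff <- function(scr_saps, quantile = 0.10) {
  if (length(scr_saps) < 10) stop("need at least 10 SCR scores")
  unname(stats::quantile(scr_saps, probs = quantile, type = 7))
}

#' Structural Distance Metric (SDM)
#'
#' `SDM = -100 * ln(w_equiv * PFTE + w_rms * (1 - RMS))` with
#' `PFTE = n_equiv / n_total` (fraction of topologically equivalent
#' positions) and `RMS = rmsd / max_rmsd`.  The log-transformed
#' equivalence/RMSD combination follows the Johnson-Sali-Blundell
#' structural distance family; rmsd is normalised by the corpus maximum
#' 24.97 Angstrom rather than the customary 3.0 so that RMS stays in
#' [0, 1].  rmsd above `max_rmsd` clamps RMS to 1 with a warning.
#'
#' @param rmsd local superposition RMSD in Angstrom.
#' @param n_equiv number of equivalenced residue pairs (> 0).
#' @param n_total total positions considered (>= `n_equiv`).
#' @param params an [sdm_params()].
#' @return numeric SDM (0 for a perfect fit with all residues
#'   equivalenced; larger means more distant).
#' @export
sdm <- function(rmsd, n_equiv, n_total, params = sdm_params()) {
  stopifnot(rmsd >= 0, n_equiv > 0, n_equiv <= n_total)
  rms <- rmsd / params$max_rmsd
  if (rms > 1) {
    warning(sprintf("rmsd %.2f exceeds max_rmsd %.2f; clamping RMS to 1",
                    rmsd, params$max_rmsd))
    rms <- 1
  }
  pfte <- n_equiv / n_total
  arg <- params$w_equiv * pfte + params$w_rms * (1 - rms)
  if (arg <= 0) stop("infinite SDM: PFTE = 0 and RMS = 1")
  -100 * log(arg)
}

#' Per-SVR score record
#'
#' Computes SAP, SCA, gap statistics and (when superposition data are
#' supplied) SDM for one PB-level alignment of an SVR.
#'
#' @param pb_aln a [pb_alignment()].
#' @param sm a `SubstitutionMatrix`.
#' @param params a [score_params()].
#' @param rmsd_local,n_equiv,n_total optional local-superposition inputs
#'   for [sdm()].
#' @param sdm_par an [sdm_params()].
#' @return object of class `SVRScores`.
#' @export
svr_scores <- function(pb_aln, sm, params = score_params(),
                       rmsd_local = NA_real_, n_equiv = NA_integer_,
                       n_total = NA_integer_, sdm_par = sdm_params()) {
  len <- nrow(pb_aln$columns)
  gaps <- sum(pb_aln$columns$s1 == "-" | pb_aln$columns$s2 == "-")
  pairs <- raw_pair_scores(pb_aln, sm)
  sap_v <- if (length(pairs)) mean(pairs) else NA_real_
  sca_v <- if (len) sca(pb_aln, sm, params) else NA_real_
  sdm_v <- if (is.finite(rmsd_local) && is.finite(n_equiv) &&
               n_equiv > 0) {
    sdm(rmsd_local, n_equiv, n_total, sdm_par)
  } else NA_real_
  structure(list(
    sap = sap_v, sca = sca_v,
    n_aligned_pairs = len - gaps,
    n_gap_columns = gaps,
    n_gap_openings = count_gap_openings(pb_aln),
    rmsd_local = rmsd_local, sdm = sdm_v,
    classification = if (is.finite(sap_v)) classify(sap_v, params) else
      NA_character_),
    class = "SVRScores")
}

#' Number of gap openings in a PB alignment
#'
#' Maximal gap runs counted across both rows.
#'
#' @param pb_aln a [pb_alignment()].
#' @return integer count.
#' @export
count_gap_openings <- function(pb_aln) {
  runs <- function(v) {
    r <- rle(v == "-")
    sum(r$values)
  }
  runs(pb_aln$columns$s1) + runs(pb_aln$columns$s2)
}

delta_state <- function(delta, better_is_positive = TRUE, eps = 1e-9) {
  if (is.na(delta)) return(NA_character_)
  if (abs(delta) < eps) return("equal")
  if ((delta > 0) == better_is_positive) "better" else "worse"
}

#' Compare before/after scores of one SVR
#'
#' Deltas are after minus before.  The better/equal/worse cell follows
#' the published convention: a positive score difference and a negative
#' SDM difference are improvements; equality means `|delta| < 1e-9`.
#'
#' @param before,after `SVRScores` of the same SVR.
#' @return list with the deltas, `gap_pct_delta`, and `cell`
#'   (`score`/`sdm` states); `cell$score` is judged on SAP.
#' @export
compare_scores <- function(before, after) {
  len_b <- before$n_aligned_pairs + before$n_gap_columns
  len_a <- after$n_aligned_pairs + after$n_gap_columns
  gp_b <- if (len_b) 100 * before$n_gap_columns / len_b else NA_real_
  gp_a <- if (len_a) 100 * after$n_gap_columns / len_a else NA_real_
  d_sap <- after$sap - before$sap
  d_sdm <- after$sdm - before$sdm
  list(delta_sap = d_sap,
       delta_sca = after$sca - before$sca,
       delta_sdm = d_sdm,
       delta_gap_pct = gp_a - gp_b,
       delta_gap_openings = after$n_gap_openings - before$n_gap_openings,
       cell = list(score = delta_state(d_sap, TRUE),
                   sdm = delta_state(d_sdm, FALSE)))
}
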