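# Ground-truth fixture generation: backbones built from PB strings by
# NeRF-style internal-to-Cartesian placement, rigid sub-segment
# displacements, conformational swaps and indels.  Every stage of the
# pipeline is testable against these without downloading structures.
#
# Construction rule: residue i takes its (phi, psi) from the central
# position of its PB prototype.  Overlapping windows then agree with the
# generating prototype at window centers; whether assignment recovers the
# generating string at off-center positions depends on the 5-symbol
# neighbourhood and is predicted exactly by pb_predict_assignment().

#' Ideal peptide geometry
#'
#' Standard trans-peptide bond lengths and angles used by the backbone
#' builder.
#'
#' @param n_ca,ca_c,c_n,c_o bond lengths in Angstrom.
#' @param n_ca_c,ca_c_n,c_n_ca,ca_c_o bond angles in degrees.
#' @param omega peptide torsion in degrees (180 = trans).
#' @return object of class `IdealGeometry`.
#' @export
ideal_geometry <- function(n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
                           c_o = 1.231, n_ca_c = 111.2, ca_c_n = 116.2,
                           c_n_ca = 121.7, ca_c_o = 120.5, omega = 180) {
  stopifnot(n_ca > 0, ca_c > 0, c_n > 0,
            n_ca_c > 0, n_ca_c < 180, ca_c_n > 0, ca_c_n < 180,
            c_n_ca > 0, c_n_ca < 180)
  structure(list(n_ca = n_ca, ca_c = ca_c, c_n = c_n, c_o = c_o,
                 n_ca_c = n_ca_c, ca_c_n = ca_c_n, c_n_ca = c_n_ca,
                 ca_c_o = ca_c_o, omega = omega),
            class = "IdealGeometry")
}

# central (phi, psi) of each prototype
pb_centers <- function(alphabet = pb_alphabet()) {
  p <- alphabet$prototypes
  cbind(phi = p[, 4], psi = p[, 5])
}

#' Build a backbone from a PB string
#'
#' Sequential internal-to-Cartesian (NeRF) placement with ideal geometry
#' and trans peptide bonds; residue i takes (phi, psi) from the central
#' position of prototype `pb_string[i]`.
#'
#' @param pb_string string over a..p, length >= 5 (`Z` is an error: no
#'   conformation is defined there).
#' @param geometry an [ideal_geometry()].
#' @param chain_id chain identifier for the result.
#' @param alphabet a `PBAlphabet`.
#' @return a [backbone_chain()] of poly-alanine with the requested
#'   dihedrals.
#' @export
build_backbone <- function(pb_string, geometry = ideal_geometry(),
                           chain_id = "A", alphabet = pb_alphabet()) {
  if (grepl("Z", pb_string)) {
    stop("cannot generate an undefined (Z) conformation")
  }
  stopifnot(grepl("^[a-p]+$", pb_string), nchar(pb_string) >= 5)
  s <- strsplit(pb_string, "")[[1]]
  n <- length(s)
  ctr <- pb_centers(alphabet)
  phi <- ctr[s, "phi"]
  psi <- ctr[s, "psi"]
  g <- geometry
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  th <- g$n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(th), sin(th), 0)
  for (i in 2:n) {
    N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         g$c_n, g$ca_c_n, psi[i - 1])
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                          g$n_ca, g$c_n_ca, g$omega)
    C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                         g$ca_c, g$n_ca_c, phi[i])
  }
  for (i in seq_len(n)) {
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         g$c_o, g$ca_c_o, psi[i] - 180)
  }
  res <- data.frame(seq_label = as.character(seq_len(n)),
                    resno = seq_len(n), icode = "",
                    aa = "A", stringsAsFactors = FALSE)
  backbone_chain(chain_id, res, N, CA, C, O)
}

#' Predict PB assignment of a built backbone without geometry
#'
#' For a backbone produced by [build_backbone()], the dihedral window at
#' every interior position is fully determined by the central angles of
#' the five surrounding prototypes, so the assignment can be computed by
#' angle arithmetic alone.  Used by the generator to sample
#' "transition-compatible" strings (strings guaranteed to round-trip);
#' the geometric route through [assign_pbs()] must agree with it.
#'
#' @param pb_string string over a..p.
#' @param alphabet a `PBAlphabet`.
#' @return predicted symbol string (`Z` at the two positions on each
#'   end).
#' @export
pb_predict_assignment <- function(pb_string, alphabet = pb_alphabet()) {
  s <- strsplit(pb_string, "")[[1]]
  n <- length(s)
  ctr <- pb_centers(alphabet)
  out <- rep(PB_UNDEF, n)
  if (n < 5) return(paste(out, collapse = ""))
  proto <- alphabet$prototypes
  for (i in 3:(n - 2)) {
    w <- c(ctr[s[i - 2], "psi"], ctr[s[i - 1], "phi"], ctr[s[i - 1], "psi"],
           ctr[s[i], "phi"], ctr[s[i], "psi"],
           ctr[s[i + 1], "phi"], ctr[s[i + 1], "psi"], ctr[s[i + 2], "phi"])
    d <- sqrt(rowMeans(angle_diff(matrix(w, 16, 8, byrow = TRUE), proto)^2))
    out[i] <- PB_LABELS[which.min(d)]
  }
  paste(out, collapse = "")
}

#' Sample a random PB string
#'
#' With `compatible = TRUE` (default) the string is drawn by backtracking
#' search so that every interior position is predicted to round-trip
#' (assignment of the built backbone recovers the generating symbol);
#' with `compatible = FALSE` symbols are i.i.d. uniform over a..p.
#' Randomness comes from R's RNG: seed with `set.seed()`.
#'
#' @param length string length (>= 5).
#' @param compatible restrict to transition-compatible strings.
#' @param alphabet a `PBAlphabet`.
#' @return a PB string.
#' @export
random_pb_string <- function(length, compatible = TRUE,
                             alphabet = pb_alphabet()) {
  stopifnot(length >= 5)
  if (!compatible) {
    return(paste(sample(PB_LABELS, length, replace = TRUE), collapse = ""))
  }
  ctr <- pb_centers(alphabet)
  proto <- alphabet$prototypes
  predict_at <- function(s, i) {
    w <- c(ctr[s[i - 2], "psi"], ctr[s[i - 1], "phi"], ctr[s[i - 1], "psi"],
           ctr[s[i], "phi"], ctr[s[i], "psi"],
           ctr[s[i + 1], "phi"], ctr[s[i + 1], "psi"], ctr[s[i + 2], "phi"])
    d <- sqrt(rowMeans(angle_diff(matrix(w, 16, 8, byrow = TRUE), proto)^2))
    PB_LABELS[which.min(d)]
  }
  s <- character(length)
  cand <- vector("list", length)
  k <- 1
  while (k <= length) {
    if (is.null(cand[[k]])) cand[[k]] <- sample(PB_LABELS)
    ok <- FALSE
    while (length(cand[[k]]) > 0) {
      s[k] <- cand[[k]][1]
      cand[[k]] <- cand[[k]][-1]
      # the window centred at k-2 is complete once s[k] is chosen
      if (k < 5 || predict_at(s, k - 2) == s[k - 2]) { ok <- TRUE; break }
    }
    if (ok) k <- k + 1
    else { cand[k] <- list(NULL); k <- k - 1
           if (k == 0) stop("backtracking exhausted (unsatisfiable)") }
  }
  paste(s, collapse = "")
}

#' Rigidly displace a residue range of a chain
#'
#' Atoms of the selected residues are rotated by `rotation_deg` about
#' `axis` through the segment's CA centroid and then translated.  The
#' chain is rebuilt afterwards, so junction dihedrals, chain breaks and
#' downstream PB assignment reflect the perturbation; internal dihedrals
#' of the moved segment are unchanged.
#'
#' @param chain a `BackboneChain`.
#' @param residue_range integer vector of residue indices (contiguous).
#' @param rotation_deg rotation angle in degrees.
#' @param translation length-3 vector in Angstrom.
#' @param axis rotation axis direction (default z).
#' @return the perturbed `BackboneChain` (a clash of a moved CA within
#'   1 Angstrom of a fixed CA warns, it is not an error).
#' @export
perturb_rigid <- function(chain, residue_range, rotation_deg = 0,
                          translation = c(0, 0, 0), axis = c(0, 0, 1)) {
  n <- n_residues(chain)
  stopifnot(all(residue_range >= 1), all(residue_range <= n))
  ax <- axis / sqrt(sum(axis^2))
  th <- rotation_deg * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  centroid <- colMeans(chain$CA[residue_range, , drop = FALSE])
  move <- function(xyz) {
    sweep(t(R %*% t(sweep(xyz, 2, centroid))), 2, -(centroid + translation))
  }
  for (a in c("N", "CA", "C", "O")) {
    sel <- chain[[a]][residue_range, , drop = FALSE]
    ok <- !apply(is.na(sel), 1, any)
    if (any(ok)) {
      chain[[a]][residue_range[ok], ] <- move(sel[ok, , drop = FALSE])
    }
  }
  fixed <- setdiff(seq_len(n), residue_range)
  if (length(fixed) && length(residue_range)) {
    dmin <- min(as.matrix(stats::dist(
      rbind(chain$CA[residue_range, , drop = FALSE],
            chain$CA[fixed, , drop = FALSE])))[
              seq_along(residue_range),
              length(residue_range) + seq_along(fixed)])
    if (dmin < 1.0) {
      warning(sprintf("perturbation causes CA clash (%.2f A)", dmin))
    }
  }
  backbone_chain(chain$chain_id, chain$residues,
                 chain$N, chain$CA, chain$C, chain$O)
}

#' Splice a replacement into a PB string
#'
#' Models a conformational change (equal length) or an indel (different
#' length); the result is meant for regeneration via [build_backbone()].
#'
#' @param pb_string original string.
#' @param residue_range contiguous indices to replace.
#' @param replacement PB string (any length).
#' @return spliced PB string.
#' @export
perturb_conformation <- function(pb_string, residue_range, replacement) {
  s <- strsplit(pb_string, "")[[1]]
  lo <- min(residue_range); hi <- max(residue_range)
  stopifnot(lo >= 1, hi <= length(s))
  paste0(substr(pb_string, 1, lo - 1), replacement,
         substr(pb_string, hi + 1, nchar(pb_string)))
}

# Replace the coordinates of residues `range` with a segment rebuilt from
# `new_pb` (same length as range), rigidly placed so the first residue's
# N/CA/C coincide with the original ones.  Downstream residues keep their
# coordinates, so a chain break typically opens at the downstream
# junction (that is the point: the region changed conformation).
graft_segment <- function(chain, range, new_pb,
                          geometry = ideal_geometry(),
                          alphabet = pb_alphabet()) {
  stopifnot(nchar(new_pb) == length(range), nchar(new_pb) >= 5)
  seg <- build_backbone(new_pb, geometry, chain_id = "seg",
                        alphabet = alphabet)
  first <- range[1]
  fit <- kabsch_fit(rbind(seg$N[1, ], seg$CA[1, ], seg$C[1, ]),
                    rbind(chain$N[first, ], chain$CA[first, ],
                          chain$C[first, ]))
  for (a in c("N", "CA", "C", "O")) {
    chain[[a]][range, ] <- apply_transform(fit$transform, seg[[a]])
  }
  backbone_chain(chain$chain_id, chain$residues,
                 chain$N, chain$CA, chain$C, chain$O)
}

fixture_columns_to_fasta <- function(cols, chain1, chain2, path,
                                     ids = c("chain1", "chain2")) {
  aa1 <- strsplit(chain_sequence(chain1), "")[[1]]
  aa2 <- strsplit(chain_sequence(chain2), "")[[1]]
  g1 <- ifelse(is.na(cols$i1), "-", aa1[cols$i1])
  g2 <- ifelse(is.na(cols$i2), "-", aa2[cols$i2])
  write_fasta(setNames(c(paste(g1, collapse = ""),
                         paste(g2, collapse = "")), ids), path)
}

#' Generate a ground-truth structure-pair fixture
#'
#' Writes two PDB files, an aligned amino acid FASTA (the "initial"
#' residue alignment, playing the role of a rigid-body aligner's output)
#' and a truth TSV stating the expected SVR residue span of chain 1 and
#' the expected classification of that SVR after PB re-alignment.
#'
#' Kinds:
#' * `identical` - two copies; the truth is zero SVRs.
#' * `displaced` - an interior helix rigidly displaced in chain 2 and
#'   mis-registered (shifted by two) in the initial alignment, the
#'   scenario where local similarity is obscured by a global fit:
#'   expected classification `similar`.
#' * `conformational` - the interior helix replaced by an extended
#'   (strand) conformation in chain 2: expected `dissimilar`.
#' * `indel` - the helix lengthened by two residues in chain 2:
#'   expected `similar`, with gaps required in the refined alignment.
#'
#' @param kind one of `identical`, `displaced`, `conformational`,
#'   `indel`.
#' @param seed integer seed controlling every random choice.
#' @param dir output directory (created if needed).
#' @return list with file paths (`pdb1`, `pdb2`, `alignment`,
#'   `truth_file`),
#'   the two chains, the alignment column table, and the truth record.
#' @export
make_pair_fixture <- function(kind = c("displaced", "conformational",
                                       "indel", "identical"),
                              seed = 1, dir = tempfile("fixture")) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  f1 <- sample(14:18, 1)          # flank lengths (residues)
  f2 <- sample(14:18, 1)
  h <- sample(8:11, 1)            # helix length
  helix <- paste(rep("m", h), collapse = "")
  core1 <- paste0("kl", helix, "nop")     # capped helix
  s1 <- paste0(strrep("d", f1), core1, strrep("d", f2))
  chain1 <- build_backbone(s1, chain_id = "A")
  n1 <- nchar(s1)
  core_lo <- f1 + 1
  core_hi <- f1 + nchar(core1)
  truth <- list(kind = kind, seed = seed,
                svr_res_lo = core_lo, svr_res_hi = core_hi)

  if (kind == "identical") {
    chain2 <- build_backbone(s1, chain_id = "B")
    cols <- data.frame(i1 = 1:n1, i2 = 1:n1)
    truth$expected_classification <- "none"
    truth$expected_svrs <- 0L
  } else if (kind == "displaced") {
    chain2 <- build_backbone(s1, chain_id = "B")
    dir3 <- stats::rnorm(3)
    dir3 <- dir3 / sqrt(sum(dir3^2))
    mag <- stats::runif(1, 5, 8)
    chain2 <- perturb_rigid(chain2, core_lo:core_hi,
                            rotation_deg = stats::runif(1, 0, 15),
                            translation = dir3 * mag,
                            axis = stats::rnorm(3))
    # initial alignment mis-registered by 2 inside the displaced region,
    # mimicking inaccurate equivalences where deviation is high
    cols <- rbind(
      data.frame(i1 = 1:f1, i2 = 1:f1),
      data.frame(i1 = c(core_lo, core_lo + 1), i2 = NA_integer_),
      data.frame(i1 = (core_lo + 2):core_hi,
                 i2 = core_lo:(core_hi - 2)),
      data.frame(i1 = NA_integer_, i2 = c(core_hi - 1, core_hi)),
      data.frame(i1 = (core_hi + 1):n1, i2 = (core_hi + 1):n1))
    truth$expected_classification <- "similar"
    truth$expected_svrs <- 1L
  } else if (kind == "conformational") {
    s2 <- perturb_conformation(s1, core_lo:core_hi,
                               paste(rep("d", nchar(core1)), collapse = ""))
    chain2 <- build_backbone(s1, chain_id = "B")   # same scaffold
    chain2 <- graft_segment(chain2, core_lo:core_hi,
                            paste(rep("d", nchar(core1)), collapse = ""))
    cols <- data.frame(i1 = 1:n1, i2 = 1:n1)
    truth$expected_classification <- "dissimilar"
    truth$expected_svrs <- 1L
  } else { # indel: helix two residues longer in chain 2
    core2 <- paste0("kl", strrep("m", h + 2), "nop")
    s2 <- paste0(strrep("d", f1), core2, strrep("d", f2))
    chain2full <- build_backbone(s2, chain_id = "B")
    # graft the longer core onto chain 1's scaffold at the core start
    chain2 <- build_backbone(s1, chain_id = "B")
    chain2 <- insert_residues(chain2, chain2full, core_lo,
                              nchar(core2))
    mid <- core_lo + nchar(core1) %/% 2
    cols <- rbind(
      data.frame(i1 = 1:(mid - 1), i2 = 1:(mid - 1)),
      data.frame(i1 = NA_integer_, i2 = c(mid, mid + 1)),
      data.frame(i1 = mid:n1, i2 = (mid + 2):(n1 + 2)))
    truth$expected_classification <- "similar"
    truth$expected_svrs <- 1L
  }

  paths <- list(pdb1 = file.path(dir, "chain1.pdb"),
                pdb2 = file.path(dir, "chain2.pdb"),
                alignment = file.path(dir, "alignment.fasta"),
                truth_file = file.path(dir, "truth.tsv"))
  write_pdb(chain1, paths$pdb1)
  write_pdb(chain2, paths$pdb2)
  fixture_columns_to_fasta(cols, chain1, chain2, paths$alignment)
  utils::write.table(as.data.frame(truth), paths$truth_file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  c(paths, list(chain1 = chain1, chain2 = chain2, columns = cols,
                truth = truth, dir = dir))
}

# chain2 scaffold with the segment starting at `at` replaced by the
# equivalent (longer) segment of `donor`, rigidly matched at the segment
# start; downstream residues of the scaffold are discarded in favour of
# the donor's (renumbered) tail geometry, keeping flank-2 internal
# geometry identical to chain 1's.
insert_residues <- function(scaffold, donor, at, seg_len) {
  fit <- kabsch_fit(rbind(donor$N[at, ], donor$CA[at, ], donor$C[at, ]),
                    rbind(scaffold$N[at, ], scaffold$CA[at, ],
                          scaffold$C[at, ]))
  n_new <- n_residues(donor)
  N <- CA <- C <- O <- matrix(NA_real_, n_new, 3)
  keep <- seq_len(at - 1)
  for (a in c("N", "CA", "C", "O")) {
    m <- get(a)
    m[keep, ] <- scaffold[[a]][keep, , drop = FALSE]
    m[at:n_new, ] <- apply_transform(fit$transform,
                                     donor[[a]][at:n_new, , drop = FALSE])
    assign(a, m)
  }
  res <- data.frame(seq_label = as.character(seq_len(n_new)),
                    resno = seq_len(n_new), icode = "", aa = "A",
                    stringsAsFactors = FALSE)
  backbone_chain(scaffold$chain_id, res, N, CA, C, O)
}
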