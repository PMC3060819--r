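# Rigid-body superposition (Kabsch least-squares fit, reflection
# excluded), RMSD, and per-column CA deviations of a paired alignment.

#' Rigid transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (Angstrom).
#' @return object of class `RigidTransform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a `RigidTransform`.
#' @param xyz n x 3 matrix (or length-3 vector).
#' @return transformed coordinates, same shape.
#' @export
apply_transform <- function(transform, xyz) {
  if (is.null(dim(xyz))) {
    return(c(transform$rotation %*% xyz) + transform$translation)
  }
  t(transform$rotation %*% t(xyz)) +
    matrix(transform$translation, nrow(xyz), 3, byrow = TRUE)
}

#' Apply a rigid transform to a whole BackboneChain
#'
#' @param transform a `RigidTransform`.
#' @param chain a `BackboneChain`.
#' @return the transformed chain (dihedrals unchanged by construction).
#' @export
transform_chain <- function(transform, chain) {
  for (a in c("N", "CA", "C", "O")) {
    ok <- !apply(is.na(chain[[a]]), 1, any)
    if (any(ok)) {
      chain[[a]][ok, ] <- apply_transform(transform,
                                          chain[[a]][ok, , drop = FALSE])
    }
  }
  chain
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `moving` onto `fixed`; reflections are excluded by flipping the sign of
#' the smallest singular vector when needed.
#'
#' @param moving,fixed n x 3 coordinate matrices, n >= 3, paired row-wise.
#' @return list with `transform` (a [rigid_transform()]) and `rmsd`
#'   (Angstrom, after the fit).
#' @export
kabsch_fit <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed)) stop("point lists differ in length")
  if (nrow(moving) < 3) stop("underdetermined fit: need at least 3 points")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  X <- sweep(moving, 2, cm); Y <- sweep(fixed, 2, cf)
  H <- crossprod(X, Y)                     # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1                       # degenerate (planar/collinear)
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cf - c(R %*% cm)
  tr <- rigid_transform(R, t_vec)
  moved <- apply_transform(tr, moving)
  list(transform = tr, rmsd = sqrt(mean(rowSums((moved - fixed)^2))))
}

#' Per-column CA deviations of a residue-pair alignment
#'
#' Euclidean CA-CA distance per alignment column after applying
#' `transform` to the second chain; `NA` for gap columns or columns whose
#' residue lacks a CA.
#'
#' @param alignment a [residue_pair_alignment()].
#' @param chain1,chain2 the two `BackboneChain`s.
#' @param transform `RigidTransform` applied to `chain2` (identity to
#'   measure raw coordinates).
#' @return numeric vector, one value (or `NA`) per alignment column.
#' @export
column_deviations <- function(alignment, chain1, chain2,
                              transform = rigid_transform()) {
  ca2 <- apply_transform(transform, chain2$CA)
  dev <- rep(NA_real_, nrow(alignment$columns))
  for (k in seq_len(nrow(alignment$columns))) {
    i <- alignment$columns$i1[k]; j <- alignment$columns$i2[k]
    if (is.na(i) || is.na(j)) next
    a <- chain1$CA[i, ]; b <- ca2[j, ]
    if (any(is.na(a)) || any(is.na(b))) next
    dev[k] <- sqrt(sum((a - b)^2))
  }
  dev
}

#' Fit chain2 onto chain1 over a set of alignment columns
#'
#' @param alignment a [residue_pair_alignment()].
#' @param chain1,chain2 the two `BackboneChain`s.
#' @param columns indices of alignment columns to fit on (default: all
#'   non-gap columns).
#' @return as [kabsch_fit()]; errors if fewer than 3 usable columns.
#' @export
fit_on_columns <- function(alignment, chain1, chain2, columns = NULL) {
  cols <- alignment$columns
  if (is.null(columns)) columns <- seq_len(nrow(cols))
  use <- columns[!is.na(cols$i1[columns]) & !is.na(cols$i2[columns])]
  if (length(use) < 3) stop("underdetermined fit: need at least 3 pairs")
  kabsch_fit(chain2$CA[cols$i2[use], , drop = FALSE],
             chain1$CA[cols$i1[use], , drop = FALSE])
}

#' Outlier-trimmed global fit
#'
#' Rigid-body core-fitting: starting from the all-column least-squares
#' fit and from fits on sliding windows of columns, iteratively refit on
#' the columns whose deviation is below `cutoff` until each start
#' converges, then keep the solution covering the largest number of
#' sub-cutoff columns (ties: lowest RMSD over them).  A single
#' least-squares pass can be tilted badly by one large displacement;
#' maximising the count of well-fitting positions recovers the conserved
#' core regardless.
#'
#' @param alignment a [residue_pair_alignment()].
#' @param chain1,chain2 the two `BackboneChain`s.
#' @param cutoff deviation cutoff in Angstrom (default 3.0).
#' @param max_iter iteration limit per start.
#' @param window,step sliding-window seed size and stride (columns).
#' @return as [kabsch_fit()]; falls back to the all-column fit when no
#'   start retains 3 sub-cutoff columns.
#' @export
trimmed_fit <- function(alignment, chain1, chain2, cutoff = 3.0,
                        max_iter = 20, window = 12, step = 6) {
  cols <- alignment$columns
  paired <- which(!is.na(cols$i1) & !is.na(cols$i2))
  seeds <- list(paired)
  if (length(paired) > window) {
    for (s in seq(1, length(paired) - window + 1, by = step)) {
      seeds[[length(seeds) + 1]] <- paired[s:(s + window - 1)]
    }
  }
  best <- NULL; best_n <- -1L; best_rmsd <- Inf
  for (seed_cols in seeds) {
    if (length(seed_cols) < 3) next
    fit <- fit_on_columns(alignment, chain1, chain2, seed_cols)
    prev <- integer(0)
    for (it in seq_len(max_iter)) {
      dev <- column_deviations(alignment, chain1, chain2, fit$transform)
      use <- which(!is.na(dev) & dev < cutoff)
      if (length(use) < 3 || identical(use, prev)) break
      fit <- fit_on_columns(alignment, chain1, chain2, use)
      prev <- use
    }
    dev <- column_deviations(alignment, chain1, chain2, fit$transform)
    use <- which(!is.na(dev) & dev < cutoff)
    n <- length(use)
    r <- if (n) sqrt(mean(dev[use]^2)) else Inf
    if (n > best_n || (n == best_n && r < best_rmsd - 1e-12)) {
      best <- fit; best_n <- n; best_rmsd <- r
    }
  }
  if (best_n < 3) return(fit_on_columns(alignment, chain1, chain2))
  best
}
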