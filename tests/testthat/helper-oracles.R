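# Independent oracles used across the suite.  Each re-derives a quantity
# by a different route than the package implementation.

# --- dihedral via the atan2(cross, dot) construction -------------------
oracle_dihedral <- function(p1, p2, p3, p4) {
  u1 <- p2 - p1; u2 <- p3 - p2; u3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(u1, u2); n2 <- cr(u2, u3)
  y <- sum(cr(n1, n2) * u2 / sqrt(sum(u2^2)))
  x <- sum(n1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# --- quaternion (Davenport K-matrix) superposition RMSD ----------------
# Independent of the SVD route: the optimal superposition RMSD follows
# from the largest eigenvalue of the 4x4 key matrix.
oracle_quaternion_rmsd <- function(moving, fixed) {
  n <- nrow(moving)
  X <- sweep(moving, 2, colMeans(moving))
  Y <- sweep(fixed, 2, colMeans(fixed))
  S <- crossprod(X, Y)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  g <- sum(X^2) + sum(Y^2)
  sqrt(max(0, (g - 2 * lam) / n))
}

# --- exhaustive enumeration of global affine-gap alignments ------------
# Scores every possible global alignment (move sequences without
# gap/gap columns) and returns the maximum; gap runs cost
# open + (L-1) * extend, terminal runs cost 0 when end_pen = FALSE.
oracle_align_score <- function(s1, s2, sm, gap_open = 10,
                               gap_extend = 0.2, end_pen = TRUE) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  sc <- function(x, y) if (x == "Z" || y == "Z") 0 else sm$scaled[x, y]
  best <- -Inf
  # moves: 1 = match, 2 = a vs gap, 3 = gap vs b
  rec <- function(i, j, prev, acc) {
    if (i == n && j == m) {
      best <<- max(best, acc)
      return(invisible(NULL))
    }
    if (i < n && j < m) rec(i + 1, j + 1, 1L, acc + sc(a[i + 1], b[j + 1]))
    if (i < n) {
      open <- prev != 2L
      cost <- if (!end_pen && j == m) 0 else
        if (open) gap_open else gap_extend
      rec(i + 1, j, 2L, acc - cost)
    }
    if (j < m) {
      open <- prev != 3L
      cost <- if (!end_pen && i == n) 0 else
        if (open) gap_open else gap_extend
      rec(i, j + 1, 3L, acc - cost)
    }
    invisible(NULL)
  }
  if (n == 0 && m == 0) return(0)
  rec(0L, 0L, 0L, 0)
  best
}

# leading-gap handling for end_pen = FALSE: a run starting at (0,0) is
# terminal too.  The closure above charges it; wrap to fix by trying all
# leading-run lengths explicitly.
oracle_align_score_free_ends <- function(s1, s2, sm, gap_open = 10,
                                         gap_extend = 0.2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  best <- -Inf
  for (la in 0:n) for (lb in 0:m) {       # free leading gaps
    if (la > 0 && lb > 0) next
    core <- oracle_align_score(
      paste(a[seq_len(n) > la], collapse = ""),
      paste(b[seq_len(m) > lb], collapse = ""),
      sm, gap_open, gap_extend, end_pen = FALSE)
    best <- max(best, core)
  }
  best
}

# --- naive per-column SAP / SCA ----------------------------------------
oracle_sap_sca <- function(pb_aln, sm, gap_score = -3) {
  s1 <- pb_aln$columns$s1; s2 <- pb_aln$columns$s2
  tot <- 0; npair <- 0; ngap <- 0
  for (k in seq_along(s1)) {
    if (s1[k] == "-" || s2[k] == "-") { ngap <- ngap + 1; next }
    if (s1[k] == "Z" || s2[k] == "Z") next
    tot <- tot + sm$raw[s1[k], s2[k]]; npair <- npair + 1
  }
  list(sap = if (npair) tot / npair else NA_real_,
       sca = (tot + gap_score * ngap) / length(s1))
}

# --- rule-literal segmentation -----------------------------------------
# SCR: >= min_len consecutive columns, each non-gap with deviation
# strictly below cutoff; everything else is SVR.
oracle_segment <- function(gapless, deviations, cutoff = 3,
                           min_len = 3) {
  n <- length(deviations)
  eligible <- gapless & !is.na(deviations) & deviations < cutoff
  is_scr <- rep(FALSE, n)
  i <- 1
  while (i <= n) {
    if (eligible[i]) {
      j <- i
      while (j < n && eligible[j + 1]) j <- j + 1
      if (j - i + 1 >= min_len) is_scr[i:j] <- TRUE
      i <- j + 1
    } else i <- i + 1
  }
  is_scr
}

# --- random rigid transforms -------------------------------------------
random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    if (sqrt(sum(q^2)) > 1e-3) break
  }
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# small identity-like substitution matrix used in scoring tests
toy_matrix <- function(diag_val = 5, off = -1) {
  m <- matrix(off, 16, 16, dimnames = list(letters[1:16], letters[1:16]))
  diag(m) <- diag_val
  substitution_matrix(m, "toy")
}

# dictionary-count oracle for PB pair counting
oracle_pair_counts <- function(alns) {
  counts <- new.env()
  for (al in alns) {
    if (is.null(al)) next
    for (k in seq_len(nrow(al$columns))) {
      x <- al$columns$s1[k]; y <- al$columns$s2[k]
      if (!x %in% letters[1:16] || !y %in% letters[1:16]) next
      key <- paste(sort(c(x, y)), collapse = "")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  m <- matrix(0L, 16, 16, dimnames = list(letters[1:16], letters[1:16]))
  for (key in ls(counts)) {
    x <- substr(key, 1, 1); y <- substr(key, 2, 2)
    m[x, y] <- m[x, y] + counts[[key]]
    if (x != y) m[y, x] <- m[y, x] + counts[[key]]
  }
  m
}
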