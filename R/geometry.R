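# Low-level vector geometry shared by the backbone reader, the
# superposition engine and the synthetic-backbone builder.

#' Wrap an angular difference into [0, 180]
#'
#' Absolute difference between two angles in degrees, measured along the
#' shorter arc of the circle, so that 179 vs -179 gives 2 and not 358.
#'
#' @param a,b angles in degrees.
#' @return non-negative difference in degrees, in `[0, 180]`.
#' @export
angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: a trans (antiperiplanar) arrangement scores 180,
#' cis scores 0.  Result lies in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Cartesian, any length unit).
#' @return dihedral angle in degrees.
#' @export
compute_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("undefined dihedral: three of the four points are collinear")
  }
  m1 <- cross3(b2 / sqrt(sum(b2^2)), n1)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  # atan2 returns (-180, 180]; map -180 to +180 for the IUPAC convention
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three previously placed atoms `a`, `b`, `c`, returns the position
#' of atom `d` such that dist(c, d) = `length`, angle(b, c, d) = `angle`
#' and dihedral(a, b, c, d) = `dihedral`.
#'
#' @param a,b,c numeric 3-vectors of the three reference atoms.
#' @param length bond length c-d in Angstrom.
#' @param angle bond angle b-c-d in degrees.
#' @param dihedral torsion a-b-c-d in degrees.
#' @return numeric 3-vector.
#' @keywords internal
nerf_place <- function(a, b, c, length, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  # local displacement in the frame of the last three atoms
  d_local <- length * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  rot <- cbind(bc, m, n)          # columns: local x, y, z in world coords
  c(rot %*% d_local) + c
}
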