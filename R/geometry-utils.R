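# Small 3D geometry helpers shared by the builders and detectors.
# All coordinates are plain numeric length-3 vectors or n x 3 matrices, in
# angstroms; angles in degrees.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) v / vnorm(v)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle at vertex b of the triple a-b-c, degrees
#' @noRd
angle3 <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Angle between two direction vectors, degrees
#' @noRd
vec_angle <- function(u, v) {
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Dihedral a-b-c-d, degrees, IUPAC sign convention
#' @noRd
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  c1 <- cross3(b1, b2); c2 <- cross3(b2, b3)
  x <- sum(c1 * c2)
  y <- sum(cross3(c1, c2) * b2 / vnorm(b2))
  atan2(y, x) * 180 / pi
}

#' Place atom D from internal coordinates relative to a-b-c
#'
#' Returns the position at distance `bond` from c, with angle(b,c,D) =
#' `angle` and dihedral(a,b,c,D) = `dihedral` (degrees, IUPAC sign).
#' @noRd
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit(c - b)
  ab <- b - a
  n <- ab - sum(ab * bc) * bc
  n <- unit(n)
  m <- cross3(bc, n)
  c + (-bond * cos(ang)) * bc +
    (bond * sin(ang) * cos(dih)) * (-n) +
    (-bond * sin(ang) * sin(dih)) * m
}

#' Quasi-uniform points on the unit sphere (Fibonacci spiral)
#' @noRd
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Random rigid-body transform (for invariance testing and fixtures)
#'
#' Draws a uniform random rotation (QR of a Gaussian matrix, det +1) and a
#' translation, and returns a function that maps an n x 3 matrix.
#'
#' @param seed integer seed
#' @param max_shift largest translation component, angstroms
#' @return function(xyz) -> transformed n x 3 matrix
#' @export
random_rigid_transform <- function(seed = 1L, max_shift = 50) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  t <- runif(3, -max_shift, max_shift)
  function(xyz) {
    xyz <- rbind(xyz)  # tolerate a bare vector
    sweep(xyz %*% t(Q), 2, -t)
  }
}

#' Apply a rigid transform to every coordinate in a structure
#'
#' @param structure a `protein_structure`
#' @param transform a function n x 3 -> n x 3, e.g. from
#'   [random_rigid_transform()]
#' @return the transformed structure
#' @export
transform_structure <- function(structure, transform) {
  stopifnot(inherits(structure, "protein_structure"))
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  structure$atoms[, c("x", "y", "z")] <- transform(xyz)
  if (!is.null(structure$solvent) && nrow(structure$solvent) > 0) {
    sxyz <- as.matrix(structure$solvent[, c("x", "y", "z")])
    structure$solvent[, c("x", "y", "z")] <- transform(sxyz)
  }
  structure
}
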