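# Low-level vector geometry: angles, dihedrals, NeRF placement, Kabsch fits.
# All angles in degrees, all coordinates in Angstrom.

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

.vnorm <- function(v) sqrt(sum(v * v))
.unit <- function(v) v / .vnorm(v)
.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Bond angle at p2 (degrees)
#' @param p1,p2,p3 3-vectors (Angstrom).
#' @return Angle p1-p2-p3 in degrees.
#' @export
bondAngle <- function(p1, p2, p3) {
  u <- .unit(p1 - p2); v <- .unit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * .rad2deg
}

#' Torsion angle of four points (degrees, IUPAC sign convention)
#' @param p1,p2,p3,p4 3-vectors (Angstrom).
#' @return Dihedral p1-p2-p3-p4 in (-180, 180].
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, .unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * .rad2deg
}

# Place atom D given torsion reference A, angle reference B, parent C:
# |D-C| = r, angle(D,C,B) = theta, dihedral(A,B,C,D) = tau (degrees).
.nerf_place <- function(A, B, C, r, theta, tau) {
  th <- theta * .deg2rad; ta <- tau * .deg2rad
  bc <- .unit(C - B)
  n <- .cross3(B - A, bc)
  n <- .unit(n)
  m <- .cross3(n, bc)
  C + r * (-cos(th) * bc + sin(th) * (cos(ta) * m - sin(ta) * n))
}

# Rodrigues rotation of point rows `xyz` about the axis through `origin`
# with unit direction `u`, by `angle` degrees (right-hand rule).
.rotate_about_axis <- function(xyz, origin, u, angle) {
  a <- angle * .deg2rad
  ca <- cos(a); sa <- sin(a)
  x <- xyz
  x[, 1] <- x[, 1] - origin[1]; x[, 2] <- x[, 2] - origin[2]
  x[, 3] <- x[, 3] - origin[3]
  dotu <- x %*% u
  # x*ca + (u x x)*sa + u (u.x) (1-ca), via the skew matrix of u
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3)
  out <- x * ca + (x %*% K) * sa + (dotu * (1 - ca)) %*% rbind(u)
  out[, 1] <- out[, 1] + origin[1]; out[, 2] <- out[, 2] + origin[2]
  out[, 3] <- out[, 3] + origin[3]
  out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation \code{R} and translation \code{t} minimizing the
#' RMSD between \code{P \%*\% t(R) + t} and \code{Q}.
#'
#' @param P,Q n x 3 coordinate matrices with matched rows.
#' @return List with \code{R} (3 x 3), \code{t} (length 3), and \code{rmsd}
#'   after the fit.
#' @export
kabschFit <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  pbar <- colMeans(P); qbar <- colMeans(Q)
  Pc <- sweep(P, 2, pbar); Qc <- sweep(Q, 2, qbar)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- qbar - drop(R %*% pbar)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

.apply_rigid <- function(xyz, R, t) {
  sweep(xyz %*% t(R), 2, t, "+")
}
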