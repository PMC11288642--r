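# Internal 3-D geometry primitives shared by the kinematics and metrics code.
# All angles at the package surface are degrees; these helpers work in degrees
# too so that torsion bookkeeping never mixes units.

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

#' Wrap angles into [-180, 180)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into the canonical interval \code{[-180, 180)}.
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  # %% can return 360 - 180 = 180 for values within rounding of the seam
  y[y >= 180] <- -180
  y
}

#' Bond angle at b formed by a-b-c, in degrees
#' @param a,b,c numeric xyz vectors.
#' @keywords internal
angle_deg <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) * .rad2deg
}

#' Dihedral angle of four points, in degrees
#'
#' Standard atan2 formulation; result in [-180, 180). The sign follows the
#' IUPAC convention (clockwise positive looking from b2 to b3).
#'
#' @param p1,p2,p3,p4 numeric xyz vectors.
#' @return dihedral in degrees.
#' @export
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(atan2(y, x) * .rad2deg)
}

# Natural-extension-reference-frame placement: position d with |d-c| = dist,
# angle(b,c,d) = ang and dihedral(a,b,c,d) = tors (degrees).
place_atom <- function(a, b, c, dist, ang, tors) {
  bc <- unitv(c - b)
  n <- c((b - a)[2] * bc[3] - (b - a)[3] * bc[2],
         (b - a)[3] * bc[1] - (b - a)[1] * bc[3],
         (b - a)[1] * bc[2] - (b - a)[2] * bc[1])
  n <- unitv(n)
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  ang_r <- ang * .deg2rad
  tor_r <- tors * .deg2rad
  d2 <- dist * c(-cos(ang_r), sin(ang_r) * cos(tor_r), -sin(ang_r) * sin(tor_r))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rodrigues rotation matrix about unit axis by angle degrees.
rotation_about_axis <- function(axis, ang) {
  u <- unitv(axis)
  th <- ang * .deg2rad
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux * ux * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy * uy * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz * uz * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# Rotate rows of xyz (n x 3) about the axis through `origin` with direction
# `axis` by `ang` degrees.
rotate_points <- function(xyz, origin, axis, ang) {
  R <- rotation_about_axis(axis, ang)
  shifted <- sweep(xyz, 2, origin)
  sweep(shifted %*% t(R), 2, origin, FUN = "+")
}
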