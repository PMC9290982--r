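# Vector and internal-coordinate geometry used by the builders and the
# hydrogen-bond, superposition and rotamer machinery.  All angles are in
# degrees, all distances in Angstrom.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

unit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  a / n
}

#' Bond angle defined by three points
#'
#' @param a,b,c Numeric 3-vectors; the angle is measured at `b`.
#' @return Angle in degrees in `[0, 180]`.
#' @export
bond_angle <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Torsion (dihedral) angle defined by four points
#'
#' Follows the IUPAC convention: looking from `b` to `c`, the angle is the
#' clockwise rotation taking the projection of `a` onto the projection of
#' `d`; cis is 0, trans is 180.
#'
#' @param a,b,c,d Numeric 3-vectors.
#' @return Angle in degrees in `(-180, 180]`.
#' @export
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# NeRF (natural extension reference frame) placement: position atom D bonded
# to C, given the chain A-B-C, the C-D bond length, the B-C-D bond angle and
# the A-B-C-D torsion.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  bc <- unit(c - b)
  n <- unit(vcross(b - a, bc))
  m <- cbind(bc, vcross(n, bc), n)
  as.numeric(m %*% d2 + c)
}

# Rotation matrix for a rotation of `theta` degrees about the (unit) axis.
rotation_matrix <- function(axis, theta) {
  u <- unit(axis)
  th <- deg2rad(theta)
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(
    ct + ux^2 * (1 - ct),       ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),       uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3L, byrow = TRUE)
}

# Rotate an n x 3 coordinate block about an axis through `origin`.
rotate_about_axis <- function(xyz, origin, axis, theta) {
  r <- rotation_matrix(axis, theta)
  sweep(sweep(xyz, 2L, origin) %*% t(r), 2L, origin, `+`)
}

# Principal axis of an n x 3 point set (first right singular vector of the
# centred coordinates), oriented so that it points along increasing point
# index on average.
fit_axis <- function(xyz) {
  ctr <- colMeans(xyz)
  s <- svd(sweep(xyz, 2L, ctr))
  ax <- s$v[, 1L]
  drift <- xyz[nrow(xyz), ] - xyz[1L, ]
  if (sum(ax * drift) < 0) ax <- -ax
  list(center = ctr, axis = ax)
}

# Unit vector v satisfying angle(u1, v) = theta1, angle(u2, v) = theta2 with
# chirality sign s for the (u1 x u2) component.  Used to place CB from the
# CA frame.
solve_direction <- function(u1, u2, theta1, theta2, s = 1) {
  c1 <- cos(deg2rad(theta1))
  c2 <- cos(deg2rad(theta2))
  d <- sum(u1 * u2)
  denom <- 1 - d^2
  a <- (c1 - d * c2) / denom
  b <- (c2 - d * c1) / denom
  w <- vcross(u1, u2)
  rest <- 1 - (a^2 + b^2 + 2 * a * b * d)
  if (rest < 0) rest <- 0
  g <- s * sqrt(rest / sum(w * w))
  unit(a * u1 + b * u2 + g * w)
}
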