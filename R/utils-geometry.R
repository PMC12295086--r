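# Small 3D geometry helpers shared across modules. All coordinates in Angstrom.

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix for rotation by `angle` (radians) about unit axis.
rotation_about_axis <- function(axis, angle) {
  u <- unitv(axis)
  ca <- cos(angle); sa <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ca + ux^2 * (1 - ca),      ux * uy * (1 - ca) - uz * sa, ux * uz * (1 - ca) + uy * sa,
    uy * ux * (1 - ca) + uz * sa, ca + uy^2 * (1 - ca),      uy * uz * (1 - ca) - ux * sa,
    uz * ux * (1 - ca) - uy * sa, uz * uy * (1 - ca) + ux * sa, ca + uz^2 * (1 - ca)
  ), nrow = 3, byrow = TRUE)
}

# Uniform random rotation (uses the session RNG; caller controls the seed).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# NeRF-style internal-coordinate placement: position a new atom at `bond`
# Angstrom from c, with angle(b, c, new) = `angle` degrees and dihedral
# (a, b, c, new) = `torsion` degrees.
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(m %*% d + c)
}

# Pairwise distances between rows of two coordinate matrices.
cross_dist <- function(xa, xb) {
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  sq <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sq[sq < 0] <- 0
  sqrt(sq)
}

deg_mod360 <- function(x) ((x %% 360) + 360) %% 360
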