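# Vectorized internal-coordinate values and their Cartesian gradients.
# All angles in degrees externally; gradients carry the rad->deg factor
# where the energy terms are quadratic in degrees.

RAD2DEG <- 180 / pi

row_norm <- function(m) sqrt(rowSums(m * m))

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Bond lengths for index pairs (matrix idx: m x 2)
bond_values <- function(coords, idx) {
  if (nrow(idx) == 0L) return(numeric(0))
  row_norm(coords[idx[, 2], , drop = FALSE] - coords[idx[, 1], , drop = FALSE])
}

# Angles in degrees for index triples i-j-k (vertex j)
angle_values <- function(coords, idx) {
  if (nrow(idx) == 0L) return(numeric(0))
  u <- coords[idx[, 1], , drop = FALSE] - coords[idx[, 2], , drop = FALSE]
  v <- coords[idx[, 3], , drop = FALSE] - coords[idx[, 2], , drop = FALSE]
  nu <- row_norm(u); nv <- row_norm(v)
  if (any(nu < 1e-10) || any(nv < 1e-10))
    stop("degenerate geometry: coincident atoms in angle")
  c0 <- rowSums(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, c0))) * RAD2DEG
}

# Signed dihedrals in degrees, range (-180, 180], for quadruples i-j-k-l
torsion_values <- function(coords, idx) {
  if (nrow(idx) == 0L) return(numeric(0))
  b1 <- coords[idx[, 2], , drop = FALSE] - coords[idx[, 1], , drop = FALSE]
  b2 <- coords[idx[, 3], , drop = FALSE] - coords[idx[, 2], , drop = FALSE]
  b3 <- coords[idx[, 4], , drop = FALSE] - coords[idx[, 3], , drop = FALSE]
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  m1 <- row_cross(n1, b2 / row_norm(b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  phi <- atan2(y, x) * RAD2DEG
  # wrap -180 to +180 so the range is (-180, 180]
  ifelse(phi <= -180, phi + 360, phi)
}

#' Wrap angular differences into (-180, 180]
#' @param x numeric vector of angle differences in degrees.
#' @return wrapped differences.
#' @export
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

# d(angle)/d(coords), degrees per Angstrom. Returns list of three m x 3
# matrices (contributions of atoms i, j, k).
angle_grad <- function(coords, idx) {
  u <- coords[idx[, 1], , drop = FALSE] - coords[idx[, 2], , drop = FALSE]
  v <- coords[idx[, 3], , drop = FALSE] - coords[idx[, 2], , drop = FALSE]
  nu <- row_norm(u); nv <- row_norm(v)
  uh <- u / nu; vh <- v / nv
  c0 <- pmin(1, pmax(-1, rowSums(uh * vh)))
  s0 <- sqrt(pmax(1 - c0 * c0, 1e-16))   # guard near-collinear
  gi <- (c0 * uh - vh) / (nu * s0) * RAD2DEG
  gk <- (c0 * vh - uh) / (nv * s0) * RAD2DEG
  list(i = gi, j = -(gi + gk), k = gk)
}

# d(torsion)/d(coords), degrees per Angstrom; standard rigid-rotor formulas.
torsion_grad <- function(coords, idx) {
  b1 <- coords[idx[, 2], , drop = FALSE] - coords[idx[, 1], , drop = FALSE]
  b2 <- coords[idx[, 3], , drop = FALSE] - coords[idx[, 2], , drop = FALSE]
  b3 <- coords[idx[, 4], , drop = FALSE] - coords[idx[, 3], , drop = FALSE]
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  nb2 <- row_norm(b2)
  n1sq <- pmax(rowSums(n1 * n1), 1e-16)
  n2sq <- pmax(rowSums(n2 * n2), 1e-16)
  u1 <- (nb2 / n1sq) * n1
  u2 <- (nb2 / n2sq) * n2
  a <- rowSums(b1 * b2) / (nb2 * nb2)
  b <- rowSums(b3 * b2) / (nb2 * nb2)
  fi <- u1
  fj <- -(1 + a) * u1 - b * u2
  fk <- a * u1 + (1 + b) * u2
  fl <- -u2
  list(i = fi * RAD2DEG, j = fj * RAD2DEG, k = fk * RAD2DEG, l = fl * RAD2DEG)
}

#' Optimal-superposition RMSD between two coordinate sets
#'
#' Least-squares rigid superposition (Kabsch algorithm: rotation plus
#' translation, reflections excluded) followed by the root-mean-square
#' deviation. Symmetric in its arguments.
#'
#' @param a,b numeric N x 3 coordinate matrices with equal row counts.
#' @return scalar RMSD in Angstrom.
#' @export
superpose_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b) || ncol(a) != 3 || ncol(b) != 3)
    stop("coordinate sets must be N x 3 with equal atom counts")
  if (nrow(a) < 1L) stop("empty coordinate set")
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  sv <- svd(crossprod(bc, ac))   # 3x3
  d <- sign(det(sv$u %*% t(sv$v)))
  s <- c(1, 1, d)
  # RMSD directly from singular values avoids forming the rotation
  e0 <- sum(ac * ac) + sum(bc * bc)
  msd <- max(0, (e0 - 2 * sum(sv$d * s)) / nrow(a))
  sqrt(msd)
}

# Kabsch rotation aligning b onto a (after centering); no reflection.
kabsch_rotation <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  sv <- svd(crossprod(bc, ac))
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

# Rotation matrix taking unit vector a to unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a * a)); b <- b / sqrt(sum(b * b))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c0 <- sum(a * b)
  if (c0 > 1 - 1e-12) return(diag(3))
  if (c0 < -1 + 1e-12) {
    # pick any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * a) * a
    v <- v / sqrt(sum(v * v))
    return(axis_angle_rotation(v, pi))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c0)
}

# Rotation about unit axis by angle (radians).
axis_angle_rotation <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis * axis))
  c0 <- cos(angle); s0 <- sin(angle)
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(c0 + x * x * (1 - c0), x * y * (1 - c0) - z * s0, x * z * (1 - c0) + y * s0,
           y * x * (1 - c0) + z * s0, c0 + y * y * (1 - c0), y * z * (1 - c0) - x * s0,
           z * x * (1 - c0) - y * s0, z * y * (1 - c0) + x * s0, c0 + z * z * (1 - c0)),
         3, 3, byrow = TRUE)
}

#' Random rotation matrix
#' @param ... unused.
#' @return 3 x 3 proper rotation, uniform over SO(3) via QR of a Gaussian.
#' @export
random_rotation <- function(...) {
  q <- qr(matrix(stats::rnorm(9), 3, 3))
  r <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}
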