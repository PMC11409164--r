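# Small geometric helpers shared by the alignment, torsion and generator code.
# All coordinates are Cartesian, in Angstrom; rotations are proper (det = +1).

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation: proper rotation by `angle` (degrees, right-handed)
#' about the direction `axis`.
#'
#' @param axis numeric length-3 direction (need not be normalized).
#' @param angle rotation angle in degrees.
#' @return a 3x3 rotation matrix with determinant +1.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- unit_vec(axis)
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Uniform random rotation matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Rotation mapping unit vector a onto unit vector b (minimal rotation).
rotation_between <- function(a, b) {
  a <- unit_vec(a); b <- unit_vec(b)
  v <- cross3(a, b)
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {
    # antiparallel: rotate 180 deg about any axis orthogonal to a
    ortho <- if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0))
    return(rotation_matrix(ortho, 180))
  }
  K <- matrix(c(0, v[3], -v[2],
                -v[3], 0, v[1],
                v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Place an atom from internal coordinates
#'
#' Natural-extension (NeRF) placement: returns the position of an atom `x`
#' bonded to `c` with bond length `bond`, bond angle `x-c-b` of `angle`
#' degrees, and torsion `x-c-b-a` of `torsion` degrees (IUPAC sign
#' convention, consistent with [dihedral_angle()]).
#'
#' @param a,b,c positions of the three reference atoms (length-3 numerics).
#' @param bond bond length in Angstrom.
#' @param angle bond angle in degrees.
#' @param torsion torsion angle in degrees.
#' @return length-3 numeric position.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180    # sign matches dihedral_angle(a, b, c, x) == torsion
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- unit_vec(c - b)
  n <- unit_vec(cross3(b - a, bc))
  M <- cbind(bc, cross3(n, bc), n)
  as.numeric(c + M %*% d2)
}

#' Kabsch superposition
#'
#' Least-squares rigid superposition of point set `P` onto `Q` (rows are
#' points) using the SVD construction, constrained to a proper rotation
#' (no reflection).
#'
#' @param P,Q n x 3 matrices of corresponding points (n >= 3).
#' @return list with `R` (3x3 rotation), `t` (translation such that
#'   `P %*% t(R) + t` superposes onto `Q`), and `rmsd`.
#' @export
kabsch <- function(P, Q) {
  stopifnot(is.matrix(P), is.matrix(Q), ncol(P) == 3, ncol(Q) == 3,
            nrow(P) == nrow(Q), nrow(P) >= 3)
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  H <- t(P0) %*% Q0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_ <- qc - as.numeric(R %*% pc)
  Pfit <- P %*% t(R) + matrix(t_, nrow(P), 3, byrow = TRUE)
  list(R = R, t = t_, rmsd = sqrt(mean(rowSums((Pfit - Q)^2))))
}

# Apply a rigid transform to an n x 3 coordinate matrix.
apply_rigid <- function(X, R, t) {
  X %*% t(R) + matrix(t, nrow(X), 3, byrow = TRUE)
}

# All pairwise distances between two coordinate matrices (rows = points).
cross_dist <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Restore the RNG state on exit; runs expr under set.seed(seed).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
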