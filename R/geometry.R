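#' @useDynLib cycloscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## Elementary 3D geometry used throughout: internal-coordinate atom
## placement (NeRF), dihedral measurement, axis rotations and the Kabsch
## least-squares superposition.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Wrap an angle in degrees into (-180, 180].
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Place an atom from internal coordinates
#'
#' Given three reference positions, returns the position of atom `x` such
#' that |p-x| = `bond`, angle(a, p, x) = `angle` and dihedral(d, a, p, x) =
#' `dihedral` (standard NeRF construction).
#'
#' @param d,a,p numeric(3) positions of the dihedral, angle and bond
#'   reference atoms (the new atom is bonded to `p`).
#' @param bond bond length in Angstrom.
#' @param angle bond angle in degrees.
#' @param dihedral torsion angle d-a-p-x in degrees.
#' @return numeric(3) coordinates.
#' @keywords internal
place_atom <- function(d, a, p, bond, angle, dihedral) {
  theta <- deg2rad(angle)
  chi <- deg2rad(dihedral)
  bc <- unit(p - a)
  n <- pracma_cross(a - d, bc)
  if (vnorm(n) < 1e-10) {
    ## colinear reference frame: pick any perpendicular
    ref <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- pracma_cross(ref, bc)
  }
  n <- unit(n)
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(theta),
          bond * sin(theta) * cos(chi),
          -bond * sin(theta) * sin(chi))
  p + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Measure a dihedral angle
#'
#' @param p1,p2,p3,p4 numeric(3) atom positions.
#' @return angle in degrees in (-180, 180].
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(rad2deg(atan2(y, x)))
}

## Rotation matrix for rotation by `angle` degrees about the (unit) axis.
axis_rotation <- function(axis, angle) {
  u <- unit(axis)
  th <- deg2rad(angle)
  c1 <- cos(th); s1 <- sin(th); t1 <- 1 - c1
  matrix(c(
    c1 + u[1]^2 * t1,          u[1] * u[2] * t1 - u[3] * s1, u[1] * u[3] * t1 + u[2] * s1,
    u[1] * u[2] * t1 + u[3] * s1, c1 + u[2]^2 * t1,          u[2] * u[3] * t1 - u[1] * s1,
    u[1] * u[3] * t1 - u[2] * s1, u[2] * u[3] * t1 + u[1] * s1, c1 + u[3]^2 * t1
  ), nrow = 3, byrow = TRUE)
}

## Rotate rows `idx` of coordinate matrix `xyz` by `angle` degrees about the
## axis through points a -> b.
rotate_about_bond <- function(xyz, idx, a, b, angle) {
  R <- axis_rotation(b - a, angle)
  sub <- xyz[idx, , drop = FALSE]
  sub <- sweep(sub, 2, a)
  sub <- sub %*% t(R)
  xyz[idx, ] <- sweep(sub, 2, a, `+`)
  xyz
}

#' Kabsch least-squares superposition
#'
#' Computes the proper rigid transform (rotation + translation) that best
#' superposes `coords_b` onto `coords_a` in the least-squares sense, and the
#' RMSD of the superposed sets.  Reflections are excluded: the returned
#' rotation always has determinant +1.
#'
#' @param coords_a,coords_b N x 3 numeric matrices of matched coordinates
#'   (row i of `coords_b` corresponds to row i of `coords_a`), N >= 3.
#' @return an object of class `Superposition`: list with `rotation` (3x3),
#'   `translation` (length 3), `rmsd` (Angstrom) and `n_atoms`.  The
#'   transform maps b onto a: `x_a ~ rotation %*% x_b + translation`.
#' @examples
#' a <- matrix(rnorm(12), 4, 3)
#' s <- kabsch_superpose(a, a)
#' s$rmsd  # 0
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (ncol(coords_a) != 3L || ncol(coords_b) != 3L)
    stop("coordinate matrices must have 3 columns")
  if (nrow(coords_a) != nrow(coords_b))
    stop("coordinate sets differ in length")
  n <- nrow(coords_a)
  if (n < 3L) stop("at least 3 matched atoms are required")
  ca <- colMeans(coords_a)
  cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca)
  B <- sweep(coords_b, 2, cb)
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- ca - as.vector(R %*% cb)
  Bf <- B %*% t(R)
  rmsd <- sqrt(sum((A - Bf)^2) / n)
  structure(
    list(rotation = R, translation = t_vec, rmsd = rmsd, n_atoms = n),
    class = "Superposition"
  )
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("Superposition: %d atoms, RMSD %.3f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

## Apply a Superposition (or plain rotation/translation) to an N x 3 matrix.
apply_transform <- function(xyz, rotation, translation) {
  sweep(as.matrix(xyz) %*% t(rotation), 2, translation, `+`)
}
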