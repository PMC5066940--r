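## Elementary 3D geometry shared by every analysis stage.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle into (-180, 180]
#'
#' @param x angle(s) in degrees.
#' @return Angle(s) wrapped into the half-open interval (-180, 180].
#' @export
wrap180 <- function(x) {
  y <- x %% 360
  ifelse(y > 180, y - 360, y)
}

#' Wrap an angle into [0, 360)
#'
#' @param x angle(s) in degrees.
#' @return Angle(s) wrapped into [0, 360).
#' @export
wrap360 <- function(x) x %% 360

#' Torsion (dihedral) angle of four points
#'
#' Computes the dihedral defined by points p1-p2-p3-p4 under the IUPAC sign
#' convention: looking from p2 towards p3, a clockwise rotation of the distal
#' bond relative to the proximal one is positive.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (angstrom).
#' @param range `"signed"` maps to (-180, 180], `"unsigned"` to [0, 360).
#' @return The dihedral angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4, range = c("signed", "unsigned")) {
  range <- match.arg(range)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop("degenerate geometry: coincident consecutive points", call. = FALSE)
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("degenerate geometry: three collinear points", call. = FALSE)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * unitv(b2))
  ang <- rad2deg(atan2(y, x))
  if (range == "unsigned") wrap360(ang) else wrap180(ang)
}

## NeRF internal-coordinate placement: position a new atom `d` bonded to `c`
## with bond length, bond angle a(b,c,d) and torsion t(a,b,c,d), degrees.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Rotation matrices about fixed axes, degrees.
rot_x <- function(theta) {
  t <- deg2rad(theta)
  matrix(c(1, 0, 0,
           0, cos(t), sin(t),
           0, -sin(t), cos(t)), 3, 3)
}

rot_z <- function(theta) {
  t <- deg2rad(theta)
  matrix(c(cos(t), sin(t), 0,
           -sin(t), cos(t), 0,
           0, 0, 1), 3, 3)
}

## Kabsch: proper rotation R and translation t minimizing ||(A R' + t) - B||,
## i.e. mapping the n x 3 coordinate set A onto B.
kabsch <- function(A, B) {
  stopifnot(nrow(A) == nrow(B), ncol(A) == 3, ncol(B) == 3)
  if (nrow(A) < 3) stop("need at least 3 atoms to superpose", call. = FALSE)
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  H <- t(A0) %*% B0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- A0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B0)^2)))
  list(R = R, t = as.numeric(cb - R %*% ca), rmsd = rmsd)
}

## Nearest proper rotation to an arbitrary 3x3 matrix (used for frame means).
orthonormalize_rotation <- function(M) {
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}
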