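# Independent oracles used to cross-check the package's geometry kernels.
# Each is implemented by a different route than the code it checks.

# Dihedral via explicit plane normals and projection (praxeolitic route):
# project the outer bonds onto the plane normal to the central bond and take
# atan2 there.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b2 <- p4 - p3
  b1 <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  cr <- c(b1[2] * v[3] - b1[3] * v[2],
          b1[3] * v[1] - b1[1] * v[3],
          b1[1] * v[2] - b1[2] * v[1])
  y <- sum(cr * w)
  atan2(y, x) * 180 / pi
}

# Optimal superposition RMSD via Horn's quaternion eigen-decomposition,
# an entirely different route than the SVD-based fit.
oracle_superpose_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  M <- t(A0) %*% B0
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A0^2) + sum(B0^2) - 2 * lam) / nrow(A)
  sqrt(max(0, msd))
}

# Quaternion helpers for the frame-averaging (geodesic midpoint) oracle.
quat_from_rot <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, s / 4)
    }
  }
  q / sqrt(sum(q^2))
}

rot_from_quat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

quat_slerp <- function(q1, q2, t) {
  d <- sum(q1 * q2)
  if (d < 0) { q2 <- -q2; d <- -d }
  if (d > 1 - 1e-10) {
    q <- q1 + t * (q2 - q1)
    return(q / sqrt(sum(q^2)))
  }
  th <- acos(d)
  (sin((1 - t) * th) * q1 + sin(t * th) * q2) / sin(th)
}

# random proper rotation
random_rotation <- function() {
  q <- rnorm(4)
  rot_from_quat(q / sqrt(sum(q^2)))
}

# small ideal fixtures reused across files
ddd_seq <- "CGCGAATTCGCG"
oxog4_seq <- "CGCXAATTCGCG"
oxog10_seq <- "CGCGAATTCXCG"

# true cytosine H5-H6 reference distance of a built structure
true_ref_distance <- function(s, resi = 3, chain = "A") {
  x <- model_xyz(s, 1)
  sqrt(sum((x[paste(chain, resi, "H5", sep = ":"), ] -
              x[paste(chain, resi, "H6", sep = ":"), ])^2))
}
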