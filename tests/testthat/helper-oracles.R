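# Independent reference implementations used to check the package's
# geometry and energy code.  These deliberately use different
# formulations (explicit projections, 4x4 homogeneous matrices,
# quaternions) from the implementation under test.

# brute-force Gram-Schmidt frame via explicit projection formulas
gs_oracle <- function(n, ca, c) {
  u1 <- c - ca
  e1 <- u1 / sqrt(sum(u1^2))
  u2 <- (n - ca) - as.numeric(((n - ca) %*% e1)) * e1
  e2 <- u2 / sqrt(sum(u2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  list(R = cbind(e1, e2, e3, deparse.level = 0), t = ca)
}

# 4x4 homogeneous matrix helpers
hom4 <- function(R, t) rbind(cbind(R, t), c(0, 0, 0, 1))
hom4_of <- function(a) hom4(a$R, a$t)
hom4_apply <- function(H, x) as.numeric(H %*% c(x, 1))[1:3]

# ACD by an explicit per-term loop over homogeneous matrices
acd_oracle <- function(conf, map) {
  s <- conf
  key <- paste(s$res$chain, s$res$resno)
  gkey <- paste(map$index$chain, map$index$resno)
  rows <- match(gkey, key)
  cb <- get_cb(s)
  frames <- lapply(seq_len(nrow(s$res)), function(r)
    build_frame(s$n[r, ], s$ca[r, ], s$c[r, ]))
  total <- 0; nterm <- 0
  for (p in seq_len(nrow(map$pairs))) {
    i <- rows[match(map$pairs$i[p], map$index$gidx)]
    j <- rows[match(map$pairs$j[p], map$index$gidx)]
    Ai_inv <- solve(hom4_of(frames[[i]]))
    Aj_inv <- solve(hom4_of(frames[[j]]))
    Aij <- hom4_of(affine_from_6d(map$mode[p, ]))
    for (x in list(s$n[j, ], s$ca[j, ], s$c[j, ], cb[j, ])) {
      lhs <- hom4_apply(Ai_inv, x)
      rhs <- hom4_apply(Aij %*% Aj_inv, x)
      total <- total + sqrt(sum((lhs - rhs)^2))
      nterm <- nterm + 1
    }
  }
  total / nterm
}

# Horn's quaternion method for optimal superposition RMSD
quat_rmsd_oracle <- function(a, b) {
  ac <- scale(a, scale = FALSE); bc <- scale(b, scale = FALSE)
  M <- t(ac) %*% bc
  K <- matrix(0, 4, 4)
  K[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  K[1, 2] <- K[2, 1] <- M[2, 3] - M[3, 2]
  K[1, 3] <- K[3, 1] <- M[3, 1] - M[1, 3]
  K[1, 4] <- K[4, 1] <- M[1, 2] - M[2, 1]
  K[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  K[2, 3] <- K[3, 2] <- M[1, 2] + M[2, 1]
  K[2, 4] <- K[4, 2] <- M[1, 3] + M[3, 1]
  K[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  K[3, 4] <- K[4, 3] <- M[2, 3] + M[3, 2]
  K[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(ac^2) + sum(bc^2) - 2 * lam) / nrow(a)
  sqrt(max(0, msd))
}

# independent internal-to-Cartesian placement (rotation-matrix route)
nerf_oracle <- function(a, b, c, bond, angle, dihedral) {
  bc <- (c - b); bc <- bc / sqrt(sum(bc^2))
  ab <- (b - a); ab <- ab / sqrt(sum(ab^2))
  n <- pracma::cross(ab, bc); n <- n / sqrt(sum(n^2))
  # rotate bc by (pi - angle) about n, then by dihedral about bc
  rot <- function(u, th) {
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  d <- rot(bc, dihedral) %*% (rot(n, pi - angle) %*% bc)
  c + bond * as.numeric(d)
}

# random proper rotation via QR with sign fix
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

random_affine <- function(span = 10) {
  affine_transform(random_rotation(), stats::runif(3, -span, span))
}
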