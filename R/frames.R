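# ---- rigid transforms -------------------------------------------------------

#' Rigid (affine) transform
#'
#' A proper rigid transform: a 3x3 rotation matrix `R` (orthonormal,
#' det = +1) and a translation vector `t` in Angstrom.  Transforms map
#' residue-local coordinates to the ground (laboratory) frame:
#' `x_ground = R %*% x_local + t`.
#'
#' @param R 3x3 rotation matrix.
#' @param t Numeric translation vector of length 3 (Angstrom).
#' @param validate Check orthonormality (`t(R) %*% R = I`, `det(R) = 1`
#'   within 1e-6)?
#' @return An object of class `"affine"`: a list with elements `R` and `t`.
#' @export
#' @examples
#' affine_transform(diag(3), c(0, 0, 5))
affine_transform <- function(R, t = c(0, 0, 0), validate = TRUE) {
  R <- unname(as.matrix(R)); t <- unname(as.numeric(t))
  if (!all(dim(R) == c(3L, 3L)) || length(t) != 3L)
    stop_validation("affine transform needs a 3x3 matrix and a 3-vector")
  if (validate) {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
      stop_validation("R is not a proper rotation (orthonormality/det violated)")
  }
  structure(list(R = R, t = t), class = "affine")
}

#' @export
print.affine <- function(x, ...) {
  cat("<affine transform>\n")
  cat("rotation:\n"); print(round(x$R, 6))
  cat("translation (A):", paste(round(x$t, 4), collapse = " "), "\n")
  invisible(x)
}

#' Identity transform
#' @return An `"affine"` identity transform.
#' @export
affine_identity <- function() affine_transform(diag(3), c(0, 0, 0), validate = FALSE)

#' Compose and invert rigid transforms
#'
#' `affine_compose(a, b)` returns the transform applying `b` first then `a`
#' (`R = Ra Rb`, `t = Ra tb + ta`); `affine_invert(a)` returns the inverse
#' (`R = Ra^T`, `t = -Ra^T ta`).
#'
#' @param a,b `"affine"` transforms.
#' @return An `"affine"` transform.
#' @export
affine_compose <- function(a, b) {
  affine_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t, validate = FALSE)
}

#' @rdname affine_compose
#' @export
affine_invert <- function(a) {
  affine_transform(t(a$R), as.numeric(-t(a$R) %*% a$t), validate = FALSE)
}

#' Apply a rigid transform to points
#'
#' @param a An `"affine"` transform.
#' @param x Length-3 vector or n x 3 matrix of points (Angstrom).
#' @return Transformed points, same shape as `x`.
#' @export
affine_apply <- function(a, x) {
  if (is.matrix(x)) {
    sweep(x %*% t(a$R), 2L, a$t, "+")
  } else {
    as.numeric(a$R %*% x) + a$t
  }
}

# ---- per-residue backbone frames -------------------------------------------

#' Local backbone frame of a residue
#'
#' Builds the residue's local coordinate system from its N, CA and C atoms
#' by Gram-Schmidt: origin at CA, x-axis along CA->C, y-axis the component
#' of CA->N orthogonal to x, z = x cross y.  The returned transform maps
#' residue-local coordinates to the ground frame.
#'
#' @param n,ca,c Length-3 coordinate vectors (Angstrom).
#' @return An `"affine"` transform (frame-to-ground).
#' @export
#' @examples
#' f <- build_frame(n = c(-0.5, 1.4, 0), ca = c(0, 0, 0), c = c(1.525, 0, 0))
#' f$R  # identity for this axis-aligned arrangement
build_frame <- function(n, ca, c) {
  e1 <- c - ca
  n1 <- sqrt(sum(e1^2))
  if (n1 < 1e-8) stop_geometry("CA and C coincide; cannot build frame")
  e1 <- e1 / n1
  v2 <- (n - ca)
  v2 <- v2 - sum(v2 * e1) * e1
  n2 <- sqrt(sum(v2^2))
  if (n2 < 1e-8) stop_geometry("N, CA, C are collinear; cannot build frame")
  e2 <- v2 / n2
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  affine_transform(cbind(e1, e2, e3, deparse.level = 0), ca, validate = FALSE)
}

# Vectorized frames for m residues.  Returns list(R9, t): R9 is m x 9 with
# columns (e1x,e1y,e1z, e2x,e2y,e2z, e3x,e3y,e3z) -- the rotation COLUMNS --
# and t is the m x 3 CA coordinates.  Hot path of the ACD energy.
frames_batch <- function(n, ca, c) {
  v1 <- c - ca
  l1 <- sqrt(rowSums(v1 * v1))
  if (any(l1 < 1e-8)) stop_geometry("degenerate residue: CA and C coincide")
  e1 <- v1 / l1
  v2 <- n - ca
  v2 <- v2 - rowSums(v2 * e1) * e1
  l2 <- sqrt(rowSums(v2 * v2))
  if (any(l2 < 1e-8)) stop_geometry("degenerate residue: N, CA, C collinear")
  e2 <- v2 / l2
  e3 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  list(R9 = cbind(e1, e2, e3, deparse.level = 0), t = ca)
}

# rowwise R^T %*% d for batched frames (d: m x 3) -> local coordinates
rot_t_apply <- function(R9, d) {
  cbind(d[, 1] * R9[, 1] + d[, 2] * R9[, 2] + d[, 3] * R9[, 3],
        d[, 1] * R9[, 4] + d[, 2] * R9[, 5] + d[, 3] * R9[, 6],
        d[, 1] * R9[, 7] + d[, 2] * R9[, 8] + d[, 3] * R9[, 9],
        deparse.level = 0)
}

# rowwise R %*% p for batched frames (p: m x 3) -> ground coordinates
rot_apply <- function(R9, p) {
  cbind(p[, 1] * R9[, 1] + p[, 2] * R9[, 4] + p[, 3] * R9[, 7],
        p[, 1] * R9[, 2] + p[, 2] * R9[, 5] + p[, 3] * R9[, 8],
        p[, 1] * R9[, 3] + p[, 2] * R9[, 6] + p[, 3] * R9[, 9],
        deparse.level = 0)
}

# ---- Euler / spherical codecs ----------------------------------------------

# wrap angle(s) to [-pi, pi)
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y >= pi] <- -pi  # guard against FP roundup
  y
}

#' Rotation matrix from Euler angles
#'
#' Intrinsic ZYX factorization: `R = Rz(gamma) %*% Ry(beta) %*% Rx(alpha)`
#' (the left factor applied last).
#'
#' @param alpha,beta,gamma Euler angles in radians (rotations about the
#'   x, y and z axes respectively).
#' @return A 3x3 rotation matrix.
#' @export
#' @examples
#' euler_to_rotation(0, 0, pi / 2)
euler_to_rotation <- function(alpha, beta, gamma) {
  ca <- cos(alpha); sa <- sin(alpha)
  cb <- cos(beta);  sb <- sin(beta)
  cg <- cos(gamma); sg <- sin(gamma)
  matrix(c(
    cg * cb, sg * cb, -sb,
    cg * sb * sa - sg * ca, sg * sb * sa + cg * ca, cb * sa,
    cg * sb * ca + sg * sa, sg * sb * ca - cg * sa, cb * ca
  ), nrow = 3L)  # column-major: columns are images of x, y, z
}

#' Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_rotation()] under the ZYX factorization:
#' `beta = asin(-R[3,1])`.  At gimbal lock (`|cos beta| < 1e-8`) the
#' convention `alpha = 0` is used and the residual rotation is absorbed
#' into `gamma`; the returned triple always reconstructs `R`.
#'
#' @param R 3x3 rotation matrix (orthonormal within 1e-6, det +1).
#' @return Named numeric vector `c(alpha, beta, gamma)` in radians, with
#'   `alpha, gamma` in `[-pi, pi)` and `beta` in `[-pi/2, pi/2]`.
#' @export
rotation_to_euler <- function(R) {
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop_validation("input is not a proper rotation matrix")
  sb <- -R[3, 1]
  sb <- max(-1, min(1, sb))
  beta <- asin(sb)
  if (abs(cos(beta)) < 1e-8) {
    # gimbal lock: only gamma -+ alpha is determined; fix alpha = 0
    alpha <- 0
    gamma <- atan2(-R[1, 2], R[2, 2])
  } else {
    alpha <- atan2(R[3, 2], R[3, 3])
    gamma <- atan2(R[2, 1], R[1, 1])
  }
  c(alpha = wrap_angle(alpha), beta = beta, gamma = wrap_angle(gamma))
}

#' Spherical decomposition of a translation vector
#'
#' `r = |t|`, polar angle `theta = acos(t_z / r)` in `[0, pi]`, azimuth
#' `phi = atan2(t_y, t_x)` in `[-pi, pi)`.  The zero vector maps to
#' `(0, 0, 0)` by convention.
#'
#' @param t Numeric vector of length 3 (Angstrom).
#' @return Named numeric vector `c(r, theta, phi)`.
#' @export
translation_to_spherical <- function(t) {
  r <- sqrt(sum(t^2))
  if (r < 1e-12) return(c(r = 0, theta = 0, phi = 0))
  theta <- acos(max(-1, min(1, t[3] / r)))
  phi <- if (abs(t[1]) < 1e-15 && abs(t[2]) < 1e-15) 0 else wrap_angle(atan2(t[2], t[1]))
  c(r = r, theta = theta, phi = phi)
}

#' Translation vector from spherical coordinates
#'
#' `t = (r sin(theta) cos(phi), r sin(theta) sin(phi), r cos(theta))`.
#'
#' @param r Distance in Angstrom, `r >= 0`.
#' @param theta Polar angle in radians.
#' @param phi Azimuthal angle in radians.
#' @return Numeric vector of length 3 (Angstrom).
#' @export
spherical_to_translation <- function(r, theta, phi) {
  if (any(r < 0)) stop_validation("r must be non-negative")
  c(r * sin(theta) * cos(phi), r * sin(theta) * sin(phi), r * cos(theta))
}

# ---- 6D transform codec -----------------------------------------------------

#' 6D interaction vector between two residue frames
#'
#' Computes the relative transform `A = A_i^-1 o A_j` (mapping residue-j
#' local coordinates into residue i's frame) and encodes it as the 6D
#' vector `(alpha, beta, gamma, r, theta, phi)`: ZYX Euler angles of the
#' rotation plus spherical coordinates of the translation.  Because frame
#' origins sit on the CA atoms, `r` equals the CA(i)-CA(j) distance.
#'
#' @param frame_i,frame_j `"affine"` residue frames (local to ground).
#' @return Named numeric vector
#'   `c(alpha, beta, gamma, r, theta, phi)` (radians / Angstrom).
#' @seealso [affine_from_6d()] for the inverse.
#' @export
relative_transform <- function(frame_i, frame_j) {
  rel <- affine_compose(affine_invert(frame_i), frame_j)
  eul <- rotation_to_euler(rel$R)
  sph <- translation_to_spherical(rel$t)
  c(eul, sph)
}

#' Rigid transform from a 6D interaction vector
#'
#' Rebuilds the affine transform: rotation from the ZYX Euler angles,
#' translation from the spherical coordinates.
#'
#' @param v Numeric vector of length 6, ordered
#'   `(alpha, beta, gamma, r, theta, phi)` (radians / Angstrom).
#' @return An `"affine"` transform.
#' @export
affine_from_6d <- function(v) {
  v <- as.numeric(v)
  if (length(v) != 6L || any(!is.finite(v)))
    stop_validation("6D vector must be 6 finite numbers")
  affine_transform(euler_to_rotation(v[1], v[2], v[3]),
                   spherical_to_translation(v[4], v[5], v[6]),
                   validate = FALSE)
}
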