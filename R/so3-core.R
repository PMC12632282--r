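#' @useDynLib bayespose, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd quantile approx optimize ks.test lm coef
#'   integrate cor
#' @importFrom rlang .data
NULL

.TOL <- 1e-10

# ---- rot3: a proper rotation in SO(3) --------------------------------------

#' Construct a 3D rotation
#'
#' `rot3()` wraps a numeric 3x3 matrix as a proper rotation (orthonormal,
#' determinant +1). The matrix acts *actively* on coordinates: the rotated
#' structure is `(g o V)(x) = V(g^-1 x)`, the convention shared by every
#' operator in this package.
#'
#' @param m A numeric 3x3 matrix.
#' @param check Validate orthonormality and determinant (default `TRUE`).
#' @return An object of class `rot3` (a 3x3 matrix).
#' @examples
#' g <- rot3_axis_angle(c(0, 0, 1), pi / 2)
#' as.matrix(g) %*% c(1, 0, 0)  # maps x-axis onto y-axis
#' @export
rot3 <- function(m, check = TRUE) {
  m <- as.matrix(m)
  if (!is.numeric(m) || !all(dim(m) == c(3L, 3L)) || !all(is.finite(m)))
    stop("`m` must be a finite numeric 3x3 matrix", call. = FALSE)
  if (check) {
    if (max(abs(crossprod(m) - diag(3))) > 1e-8)
      stop("`m` is not orthonormal", call. = FALSE)
    if (abs(det(m) - 1) > 1e-8)
      stop("`m` must have determinant +1", call. = FALSE)
  }
  structure(m, class = "rot3")
}

#' @export
print.rot3 <- function(x, ...) {
  cat("<rot3> angle", format(rot3_angle(x), digits = 4), "rad\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
as.matrix.rot3 <- function(x, ...) unclass(x)

#' @rdname rot3
#' @export
rot3_identity <- function() rot3(diag(3), check = FALSE)

#' Rotation group plumbing
#'
#' Composition, inversion, and the rotation angle of a single rotation.
#' `rot3_compose(g2, g1)` is "first `g1`, then `g2`" (matrix product
#' `g2 %*% g1`); `rot3_invert` is the transpose.
#'
#' @param g,g1,g2 `rot3` objects.
#' @return A `rot3` (or, for `rot3_angle`, a numeric angle in `[0, pi]`).
#' @export
rot3_compose <- function(g2, g1) rot3(unclass(g2) %*% unclass(g1), check = FALSE)

#' @rdname rot3_compose
#' @export
rot3_invert <- function(g) rot3(t(unclass(g)), check = FALSE)

#' @rdname rot3_compose
#' @export
rot3_angle <- function(g) {
  acos(.clamp1((sum(diag(unclass(g))) - 1) / 2))
}

.clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Axis-angle, Euler and quaternion constructors
#'
#' @param axis Numeric length-3 rotation axis. Non-unit axes are normalized
#'   with a warning.
#' @param angle Rotation angle in radians; values outside `[0, 2*pi)` are
#'   reduced modulo `2*pi`.
#' @param alpha,beta,gamma ZYZ Euler angles in radians:
#'   `g = Rz(alpha) Ry(beta) Rz(gamma)`.
#' @param q Unit quaternion `c(w, x, y, z)`; non-unit input is normalized.
#' @return A `rot3`.
#' @export
rot3_axis_angle <- function(axis, angle) {
  axis <- as.numeric(axis)
  if (length(axis) != 3L || !all(is.finite(axis)) || sum(axis^2) == 0)
    stop("`axis` must be a finite non-zero 3-vector", call. = FALSE)
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-8) {
    warning("`axis` is not unit length; normalizing")
    axis <- axis / nrm
  }
  if (angle < 0 || angle >= 2 * pi) angle <- angle %% (2 * pi)
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  rot3(R, check = FALSE)
}

#' @rdname rot3_axis_angle
#' @export
rot3_euler_zyz <- function(alpha, beta, gamma) {
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  rot3(Rz(alpha) %*% Ry(beta) %*% Rz(gamma), check = FALSE)
}

#' @rdname rot3_axis_angle
#' @export
rot3_quat <- function(q) {
  q <- as.numeric(q)
  if (length(q) != 4L || !all(is.finite(q)) || sum(q^2) == 0)
    stop("`q` must be a finite non-zero 4-vector (w, x, y, z)", call. = FALSE)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z),     2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2),     2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x),     1 - 2 * (x^2 + y^2)), 3, 3)
  rot3(R, check = FALSE)
}

#' Rotation representation conversions
#'
#' `rot3_to_quat` returns the unit quaternion `c(w, x, y, z)` with the
#' first-nonzero-component-positive canonicalization (`w >= 0`;
#' ties broken toward positive `x`). `rot3_to_axis_angle` returns
#' `list(axis, angle)` with `angle` in `[0, pi]`; `rot3_to_euler_zyz` returns
#' `c(alpha, beta, gamma)` with `beta` in `[0, pi]`.
#'
#' @param g A `rot3`.
#' @return See details.
#' @export
rot3_to_quat <- function(g) {
  R <- unclass(g)
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q <- q / sqrt(sum(q^2))
  nz <- which(abs(q) > 1e-12)[1]
  if (length(nz) && q[nz] < 0) q <- -q
  q
}

#' @rdname rot3_to_quat
#' @export
rot3_to_axis_angle <- function(g) {
  q <- rot3_to_quat(g)
  angle <- 2 * acos(.clamp1(abs(q[1])))
  v <- q[2:4] * sign(if (q[1] == 0) 1 else q[1])
  nv <- sqrt(sum(v^2))
  axis <- if (nv < 1e-12) c(0, 0, 1) else v / nv
  list(axis = axis, angle = angle)
}

#' @rdname rot3_to_quat
#' @export
rot3_to_euler_zyz <- function(g) {
  R <- unclass(g)
  beta <- acos(.clamp1(R[3, 3]))
  if (sin(beta) > 1e-10) {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  } else {
    # gimbal lock: put all z-rotation into alpha
    alpha <- atan2(R[2, 1], R[1, 1])
    if (R[3, 3] < 0) alpha <- -atan2(R[2, 1], R[1, 1])
    gamma <- 0
  }
  c(alpha = alpha, beta = beta, gamma = gamma)
}

# ---- metrics ----------------------------------------------------------------

#' Chordal (Frobenius) distance between rotations
#'
#' `d_F(g1, g2) = ||g1 - g2||_F`, in `[0, 2*sqrt(2)]`. Its square equals
#' `6 - 2 tr(g2 g1^T)`, the entrywise mean-square error up to scale, and is
#' the loss the MMSE estimator minimizes in posterior expectation.
#'
#' @param g1,g2 `rot3` objects (or plain 3x3 rotation matrices).
#' @return A nonnegative scalar.
#' @export
chordal_distance <- function(g1, g2) {
  m1 <- unclass(g1); m2 <- unclass(g2)
  if (!all(is.finite(m1)) || !all(is.finite(m2)))
    stop("non-finite rotation input", call. = FALSE)
  sqrt(sum((m1 - m2)^2))
}

#' Geodesic distance between rotations
#'
#' The rotation angle of `g2 g1^-1`:
#' `d_G(g1, g2) = arccos((tr(g2 g1^-1) - 1)/2)`, in `[0, pi]`. The arccos
#' argument is clamped to `[-1, 1]` to suppress floating-point domain errors.
#'
#' @inheritParams chordal_distance
#' @return A scalar in `[0, pi]`.
#' @export
geodesic_distance <- function(g1, g2) {
  m1 <- unclass(g1); m2 <- unclass(g2)
  if (!all(is.finite(m1)) || !all(is.finite(m2)))
    stop("non-finite rotation input", call. = FALSE)
  acos(.clamp1((sum(m2 * m1) - 1) / 2))  # tr(g2 g1^T) = sum(g2 * g1)
}

# ---- orthogonal Procrustes projection ---------------------------------------

#' Project an arbitrary 3x3 matrix onto SO(3)
#'
#' Solves the orthogonal Procrustes problem
#' `argmin_{Omega in SO(3)} ||Omega - A||_F` by SVD with the determinant sign
#' correction applied to the smallest singular direction. This is the
#' "rounding" step that turns the posterior-mean matrix of the relaxed MMSE
#' problem into a proper rotation.
#'
#' The minimizer is non-unique when the sign correction is active and the two
#' smallest singular values of `A` coincide (degenerate posteriors, e.g.
#' perfectly symmetric bimodal weights, genuinely produce this). In that case
#' one minimizer is returned and the `"nonunique"` attribute is set to `TRUE`.
#'
#' @param A A finite, non-zero numeric 3x3 matrix.
#' @return A `rot3` with a logical attribute `"nonunique"`.
#' @export
procrustes_project <- function(A) {
  A <- as.matrix(unclass(A))
  if (!all(dim(A) == c(3L, 3L)) || !all(is.finite(A)))
    stop("`A` must be a finite 3x3 matrix", call. = FALSE)
  if (all(A == 0))
    stop("`A` is the zero matrix; every rotation is a minimizer", call. = FALSE)
  sv <- svd(A)
  s <- sign(det(sv$u %*% t(sv$v)))
  nonunique <- FALSE
  if (s < 0 && abs(sv$d[2] - sv$d[3]) < 1e-8) nonunique <- TRUE
  Om <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  out <- rot3(Om, check = FALSE)
  attr(out, "nonunique") <- nonunique
  out
}

# ---- vectorized internals ---------------------------------------------------

# rotations as an L x 9 row-major flattening (columns = as.vector of each 3x3)
.rots_to_flat <- function(rots) {
  # rots: 3 x 3 x L array -> L x 9
  L <- dim(rots)[3]
  t(matrix(rots, 9L, L))
}

.flat_to_rot <- function(v) rot3(matrix(v, 3, 3), check = FALSE)

# geodesic distances from one rotation to an array of rotations
.geodesic_to_all <- function(R, rots) {
  L <- dim(rots)[3]
  flat <- matrix(rots, 9L, L)
  tr <- as.numeric(as.vector(R) %*% flat)  # tr(R_l R^T) per node
  acos(.clamp1((tr - 1) / 2))
}
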