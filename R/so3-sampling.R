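# Discretizations of SO(3), Haar sampling, and the isotropic Gaussian prior.

# ---- quadrature grids -------------------------------------------------------

#' Build a quadrature grid on SO(3)
#'
#' Discretizes the rotation group as a product of a near-equal-area sphere
#' covering (viewing directions, a Fibonacci lattice of ~`L^(2/3)` points) and
#' an equispaced circular rule over the in-plane angle (~`L^(1/3)` points).
#' Each node is `Rz(phi) Ry(theta) Rz(alpha)` where `(theta, phi)` is a
#' viewing direction and `alpha` an in-plane angle; weights are equal and sum
#' to one (normalized Haar measure). The realized `L` is the nearest product
#' size to `L_target`.
#'
#' @param L_target Requested number of nodes (`>= 2`).
#' @return An object of class `so3_grid`: a list with `rotations`
#'   (a `3 x 3 x L` array), `weights`, `L`, `n_inplane`, `n_dirs`.
#' @examples
#' g <- so3_grid(300)
#' g$L
#' sum(g$weights)
#' @export
so3_grid <- function(L_target) {
  if (!is.numeric(L_target) || length(L_target) != 1L || L_target < 2)
    stop("`L_target` must be a single number >= 2", call. = FALSE)
  n1 <- max(1L, as.integer(round(L_target^(1 / 3))))
  n2 <- max(2L, as.integer(round(L_target / n1)))
  L <- n1 * n2
  dirs <- .fibonacci_sphere(n2)          # n2 x 2 matrix (theta, phi)
  alphas <- 2 * pi * (seq_len(n1) - 1) / n1
  rots <- array(0, dim = c(3, 3, L))
  ell <- 1L
  for (j in seq_len(n2)) {
    Rdir <- unclass(rot3_euler_zyz(dirs[j, 2], dirs[j, 1], 0))
    for (i in seq_len(n1)) {
      a <- alphas[i]
      Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
      rots[, , ell] <- Rdir %*% Rz
      ell <- ell + 1L
    }
  }
  structure(list(rotations = rots, weights = rep(1 / L, L), L = L,
                 n_inplane = n1, n_dirs = n2, kind = "product"),
            class = "so3_grid")
}

# Fibonacci lattice on S^2: returns (theta = colatitude, phi = azimuth)
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  theta <- acos(pmin(1, pmax(-1, z)))
  phi <- (pi * (1 + sqrt(5)) * i) %% (2 * pi)
  cbind(theta = theta, phi = phi)
}

#' @export
print.so3_grid <- function(x, ...) {
  cat("<so3_grid> L =", x$L, "(", x$n_dirs, "directions x", x$n_inplane,
      "in-plane ), kind =", x$kind, "\n")
  invisible(x)
}

#' Monte Carlo grid drawn from a prior
#'
#' Discretizes SO(3) with `L` i.i.d. nodes sampled from `prior` and equal
#' weights. Posterior expectations against this grid are importance-sampling
#' approximations of prior-weighted integrals, so the prior density must
#' *not* be applied again at the nodes: use `prior_haar()` as the working
#' prior on such a grid. This is the natural discretization for concentrated
#' priors, whose mass a uniform quadrature resolves poorly.
#'
#' @param prior An [so3_prior].
#' @param L Number of nodes.
#' @param seed Integer seed for reproducibility.
#' @return An `so3_grid` with `kind = "prior_mc"`.
#' @export
so3_grid_from_prior <- function(prior, L, seed = 1L) {
  if (L < 2) stop("`L` must be >= 2", call. = FALSE)
  rots <- switch(prior$kind,
    haar_uniform = sample_haar(L, seed = seed),
    igso3 = sample_igso3(prior$eta, L, seed = seed),
    stop("cannot sample from a tabulated prior", call. = FALSE))
  structure(list(rotations = rots, weights = rep(1 / L, L), L = L,
                 n_inplane = NA_integer_, n_dirs = NA_integer_,
                 kind = "prior_mc"),
            class = "so3_grid")
}

#' Nearest-neighbor spacing of a grid
#'
#' The maximum over nodes of the geodesic distance to the nearest other node;
#' a mesh-coarseness summary used by the high-SNR agreement checks.
#'
#' @param grid An [so3_grid].
#' @return A scalar in radians.
#' @export
grid_spacing <- function(grid) {
  flat <- matrix(grid$rotations, 9L, grid$L)
  tr <- crossprod(flat)                 # tr(R_i^T R_j)
  ang <- matrix(acos(.clamp1((tr - 1) / 2)), grid$L, grid$L)
  diag(ang) <- Inf
  max(apply(ang, 1L, min))
}

# ---- Haar sampling ----------------------------------------------------------

#' Sample Haar-uniform rotations
#'
#' I.i.d. uniform rotations via normalized quaternions drawn from an
#' isotropic 4D Gaussian.
#'
#' @param n Number of rotations.
#' @param seed Optional integer seed.
#' @return A `3 x 3 x n` array of rotation matrices.
#' @export
sample_haar <- function(n, seed = NULL) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  q <- matrix(rnorm(4L * n), 4L, n)
  q <- sweep(q, 2L, sqrt(colSums(q^2)), "/")
  .quat_to_rot_array(q)
}

# vectorized quaternion (4 x n, rows w x y z) -> 3 x 3 x n rotation array
.quat_to_rot_array <- function(q) {
  w <- q[1, ]; x <- q[2, ]; y <- q[3, ]; z <- q[4, ]
  flat <- rbind(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2))
  array(flat, dim = c(3, 3, ncol(q)))
}

# vectorized Rodrigues formula: unit axes (3 x n), angles (n) -> 3 x 3 x n
.axis_angle_to_rot_array <- function(u, ang) {
  c_ <- cos(ang); s <- sin(ang); C <- 1 - c_
  x <- u[1, ]; y <- u[2, ]; z <- u[3, ]
  flat <- rbind(
    c_ + x^2 * C,     x * y * C + z * s, x * z * C - y * s,
    x * y * C - z * s, c_ + y^2 * C,     y * z * C + x * s,
    x * z * C + y * s, y * z * C - x * s, c_ + z^2 * C)
  array(flat, dim = c(3, 3, length(ang)))
}

# ---- priors -----------------------------------------------------------------

#' Priors on SO(3)
#'
#' `prior_haar()` is the uniform (Haar) prior. `prior_igso3(eta)` is the
#' isotropic Gaussian on SO(3): axes uniform on the sphere and the rotation
#' angle drawn from the heat-kernel marginal controlled by `eta` (Haar
#' uniformity as `eta -> Inf`; concentration at the identity as `eta -> 0`).
#' `prior_tabulated(values)` carries per-node densities (relative to Haar)
#' for use with a matching grid.
#'
#' @param eta Positive concentration parameter (small = concentrated).
#' @param values Positive per-node density values.
#' @return An object of class `so3_prior`.
#' @export
prior_haar <- function() {
  structure(list(kind = "haar_uniform", eta = NULL, table = NULL),
            class = "so3_prior")
}

#' @rdname prior_haar
#' @export
prior_igso3 <- function(eta) {
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta <= 0)
    stop("`eta` must be a positive scalar", call. = FALSE)
  structure(list(kind = "igso3", eta = eta, table = NULL), class = "so3_prior")
}

#' @rdname prior_haar
#' @export
prior_tabulated <- function(values) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("tabulated densities must be finite and strictly positive",
         call. = FALSE)
  structure(list(kind = "tabulated", eta = NULL, table = values),
            class = "so3_prior")
}

#' @export
print.so3_prior <- function(x, ...) {
  cat("<so3_prior>", x$kind,
      if (x$kind == "igso3") paste0("(eta = ", x$eta, ")") else "", "\n")
  invisible(x)
}

# ---- isotropic Gaussian on SO(3) -------------------------------------------

# Heat-kernel density on SO(3) w.r.t. Haar measure, as a function of the
# rotation angle omega: sum_l (2l+1) exp(-l(l+1) eta^2 / 2) chi_l(omega),
# chi_l(omega) = sin((l+1/2) omega) / sin(omega/2). Series truncated when the
# coefficient falls below 1e-12.
.igso3_haar_density <- function(omega, eta) {
  lmax <- 0L
  while ((2 * (lmax + 1) + 1) * exp(-(lmax + 1) * (lmax + 2) * eta^2 / 2) > 1e-12 &&
         lmax < 4000L) lmax <- lmax + 1L
  out <- numeric(length(omega))
  half <- omega / 2
  s <- sin(half)
  small <- abs(s) < 1e-8
  for (l in 0:lmax) {
    coefl <- (2 * l + 1) * exp(-l * (l + 1) * eta^2 / 2)
    chi <- numeric(length(omega))
    chi[!small] <- sin((l + 0.5) * omega[!small]) / s[!small]
    chi[small] <- 2 * l + 1        # limit as omega -> 0
    out <- out + coefl * chi
  }
  pmax(out, 0)
}

#' Marginal rotation-angle density of the isotropic Gaussian on SO(3)
#'
#' The density of the rotation angle `omega` in `[0, pi]` under
#' `IG-SO(3)(eta)`: the truncated heat-kernel character series multiplied by
#' the Haar angle factor `(1 - cos omega)/pi`, normalized to integrate to one.
#'
#' @param omega Angles in `[0, pi]` (vectorized).
#' @param eta Positive concentration parameter.
#' @return Density values.
#' @export
igso3_angle_density <- function(omega, eta) {
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta <= 0)
    stop("`eta` must be a positive scalar", call. = FALSE)
  if (any(omega < -1e-12 | omega > pi + 1e-12))
    stop("`omega` must lie in [0, pi]", call. = FALSE)
  omega <- pmin(pi, pmax(0, omega))
  tab <- .igso3_table(eta)
  approx(tab$omega, tab$pdf, xout = omega, rule = 2)$y
}

# cached tabulation of the angle pdf/cdf on 4096 points
.igso3_cache <- new.env(parent = emptyenv())

.igso3_table <- function(eta) {
  key <- format(eta, digits = 17)
  if (!is.null(.igso3_cache[[key]])) return(.igso3_cache[[key]])
  om <- seq(0, pi, length.out = 4096L)
  raw <- .igso3_haar_density(om, eta) * (1 - cos(om)) / pi
  dx <- om[2] - om[1]
  Z <- sum((raw[-1] + raw[-length(raw)]) / 2) * dx   # trapezoid
  pdf <- raw / Z
  cdf <- c(0, cumsum((pdf[-1] + pdf[-length(pdf)]) / 2) * dx)
  cdf <- cdf / cdf[length(cdf)]
  tab <- list(omega = om, pdf = pdf, cdf = cdf)
  .igso3_cache[[key]] <- tab
  tab
}

#' Sample from the isotropic Gaussian on SO(3)
#'
#' Axes i.i.d. uniform on the sphere; angles by inverse-CDF sampling from
#' [igso3_angle_density()] (monotone interpolation of a 4096-point
#' tabulation, cached per `eta`).
#'
#' @param eta Positive concentration parameter.
#' @param n Number of rotations.
#' @param seed Optional integer seed.
#' @return A `3 x 3 x n` array.
#' @export
sample_igso3 <- function(eta, n, seed = NULL) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tab <- .igso3_table(eta)
  u <- runif(n)
  ang <- approx(tab$cdf, tab$omega, xout = u, rule = 2, ties = "ordered")$y
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  sz <- sqrt(pmax(0, 1 - z^2))
  u <- rbind(sz * cos(phi), sz * sin(phi), z)
  .axis_angle_to_rot_array(u, ang)
}

#' Log prior density at grid nodes
#'
#' Evaluates `log Lambda(g)` (density relative to Haar measure) at every node
#' of a grid: constant for the uniform prior; a function of each node's
#' rotation angle from the identity for the isotropic Gaussian; the stored
#' table for tabulated priors.
#'
#' @param prior An [so3_prior].
#' @param grid An [so3_grid].
#' @return A numeric vector of length `grid$L`.
#' @export
prior_log_density_at_nodes <- function(prior, grid) {
  L <- grid$L
  switch(prior$kind,
    haar_uniform = rep(0, L),
    igso3 = {
      flat <- matrix(grid$rotations, 9L, L)
      tr <- flat[1, ] + flat[5, ] + flat[9, ]
      ang <- acos(.clamp1((tr - 1) / 2))
      log(pmax(.igso3_haar_density(ang, prior$eta), 1e-300))
    },
    tabulated = {
      if (length(prior$table) != L)
        stop("tabulated prior length does not match grid size", call. = FALSE)
      log(prior$table)
    })
}

#' Sample rotations from a prior
#'
#' @param prior An [so3_prior].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return A `3 x 3 x n` array.
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  switch(prior$kind,
    haar_uniform = sample_haar(n, seed = seed),
    igso3 = sample_igso3(prior$eta, n, seed = seed),
    stop("cannot sample from a tabulated prior", call. = FALSE))
}
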