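# Measurement operators: volume rotation, tomographic projection, polar-grid
# in-plane rotation, noise injection, and observation simulation.

# ---- containers -------------------------------------------------------------

#' Density volume and polar image containers
#'
#' `vol3()` wraps a cubic `N x N x N` numeric array (electron density in
#' arbitrary units; `voxel_size` is metadata in Angstrom per voxel).
#' `polar_img()` wraps a `d x L_ang` matrix sampled on a uniform polar grid
#' (`d` radial samples by `L_ang` angular samples); in-plane rotation on this
#' layout is an exact cyclic shift of the angular axis.
#'
#' @param data A finite numeric array (3D cubic) or matrix (polar).
#' @param voxel_size Positive voxel size (3D only).
#' @return An object of class `vol3` or `polar_img`.
#' @export
vol3 <- function(data, voxel_size = 1) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  d <- dim(data)
  if (d[1] != d[2] || d[2] != d[3])
    stop("`data` must be cubic (N x N x N)", call. = FALSE)
  if (!all(is.finite(data))) stop("`data` has non-finite entries", call. = FALSE)
  if (!is.numeric(voxel_size) || voxel_size <= 0)
    stop("`voxel_size` must be positive", call. = FALSE)
  structure(data, voxel_size = voxel_size, class = "vol3")
}

#' @rdname vol3
#' @export
polar_img <- function(data) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("`data` has non-finite entries", call. = FALSE)
  structure(data, class = "polar_img")
}

#' @export
print.vol3 <- function(x, ...) {
  cat("<vol3>", dim(x)[1], "^3 voxels, voxel size",
      attr(x, "voxel_size"), "A\n")
  invisible(x)
}

#' @export
print.polar_img <- function(x, ...) {
  cat("<polar_img>", nrow(x), "radial x", ncol(x), "angular samples\n")
  invisible(x)
}

.strip <- function(x) {
  a <- unclass(x)
  attr(a, "voxel_size") <- NULL
  a
}

# ---- operators --------------------------------------------------------------

#' Rotate a volume
#'
#' Applies the active rotation `(g o V)(x) = V(g^-1 x)` by tricubic
#' (Catmull-Rom) resampling at the transformed voxel-center coordinates about
#' the volume center, zero fill outside the grid. The identity rotation
#' returns the volume bit-exactly.
#'
#' @param V A [vol3].
#' @param g A [rot3] (or 3x3 rotation matrix).
#' @return A [vol3].
#' @export
rotate_volume <- function(V, g) {
  stopifnot(inherits(V, "vol3"))
  R <- unclass(g)
  out <- cpp_resample(.strip(V), as.numeric(t(R)))  # sample at R^T (x - c) + c
  vol3(out, voxel_size = attr(V, "voxel_size"))
}

#' Project a volume along z
#'
#' The tomographic projection operator: the line integral along the beam
#' axis, implemented as the voxel sum over the third index. Total image mass
#' equals total volume mass exactly.
#'
#' @param V A [vol3].
#' @return An `N x N` numeric matrix.
#' @export
project_volume <- function(V) {
  stopifnot(inherits(V, "vol3"))
  d <- dim(V)
  a <- .strip(V)
  matrix(rowSums(matrix(a, d[1] * d[2], d[3])), d[1], d[2])
}

#' Rotate a polar image in-plane
#'
#' Cyclic shift of the angular axis by `k` samples -- the exact (no
#' interpolation) SO(2) action on the polar layout. Satisfies the group law
#' `rotate_polar(rotate_polar(img, k1), k2) = rotate_polar(img, k1 + k2)`.
#'
#' @param img A [polar_img].
#' @param k Integer angular shift (any sign; reduced modulo `L_ang`).
#' @return A [polar_img].
#' @export
rotate_polar <- function(img, k) {
  if (!inherits(img, "polar_img"))
    stop("`img` must be a polar image (see `polar_img()`)", call. = FALSE)
  La <- ncol(img)
  k <- as.integer(k) %% La
  if (k == 0L) return(img)
  idx <- ((seq_len(La) - 1L - k) %% La) + 1L   # column j of output = column j-k
  polar_img(unclass(img)[, idx, drop = FALSE])
}

#' Add white Gaussian noise
#'
#' Adds i.i.d. `N(0, sigma^2)` noise to every stored sample, in whichever
#' layout the payload uses.
#'
#' @param x A [vol3], [polar_img], or numeric array.
#' @param sigma Positive noise standard deviation.
#' @param seed Optional integer seed.
#' @return Same type as `x`.
#' @export
add_noise <- function(x, sigma, seed = NULL) {
  if (!is.numeric(sigma) || sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  noise <- rnorm(length(x), sd = sigma)
  out <- unclass(x) + noise
  if (inherits(x, "vol3")) vol3(array(out, dim(x)), attr(x, "voxel_size"))
  else if (inherits(x, "polar_img")) polar_img(matrix(out, nrow(x)))
  else {
    dim(out) <- dim(x)
    out
  }
}

#' Signal-to-noise ratio conventions
#'
#' `snr_of(x, sigma)` returns mean squared signal value over the grid divided
#' by `sigma^2`; `sigma_for_snr(x, snr)` inverts it. This is the package's
#' own SNR convention; benchmark tables report raw `sigma` alongside it.
#'
#' @param x Signal (any numeric payload).
#' @param sigma Positive noise standard deviation.
#' @param snr Positive target SNR.
#' @return A positive scalar.
#' @export
snr_of <- function(x, sigma) {
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  p <- mean(unclass(x)^2)
  if (p == 0) stop("zero signal has no SNR", call. = FALSE)
  p / sigma^2
}

#' @rdname snr_of
#' @export
sigma_for_snr <- function(x, snr) {
  if (snr <= 0) stop("`snr` must be positive", call. = FALSE)
  p <- mean(unclass(x)^2)
  if (p == 0) stop("zero signal has no SNR", call. = FALSE)
  sqrt(p / snr)
}

# ---- observations -----------------------------------------------------------

#' Simulate a noisy observation
#'
#' Draws a ground-truth rotation from `prior` (or a uniform angular index for
#' the polar model), applies the measurement chain of the chosen model --
#' `no_projection_3d`: rotate; `projection_2d`: rotate then project;
#' `polar_2d`: cyclic angular shift -- and adds white Gaussian noise of
#' standard deviation `sigma`.
#'
#' @param V A [vol3] (3D models) or [polar_img] (polar model).
#' @param prior An [so3_prior] (ignored for `polar_2d`).
#' @param sigma Positive noise standard deviation.
#' @param model One of `"no_projection_3d"`, `"projection_2d"`, `"polar_2d"`.
#' @param seed Optional integer seed.
#' @return An object of class `pose_obs`: list with `y`, `model`, `sigma`,
#'   `g_true` (a `rot3`, or `k_true` angular index for the polar model).
#' @export
simulate_observation <- function(V, prior = prior_haar(), sigma, model, seed = NULL) {
  model <- match.arg(model, c("no_projection_3d", "projection_2d", "polar_2d"))
  if (!is.null(seed)) set.seed(seed)
  if (model == "polar_2d") {
    if (!inherits(V, "polar_img"))
      stop("polar_2d model needs a polar image payload", call. = FALSE)
    k <- sample.int(ncol(V), 1L) - 1L
    y <- add_noise(rotate_polar(V, k), sigma)
    return(structure(list(y = y, model = model, sigma = sigma,
                          g_true = NULL, k_true = k), class = "pose_obs"))
  }
  if (!inherits(V, "vol3"))
    stop(model, " model needs a volume payload", call. = FALSE)
  g <- rot3(sample_prior(prior, 1L)[, , 1], check = FALSE)
  rot <- rotate_volume(V, g)
  y <- if (model == "projection_2d") project_volume(rot) else rot
  y <- add_noise(y, sigma)
  structure(list(y = y, model = model, sigma = sigma, g_true = g,
                 k_true = NULL), class = "pose_obs")
}

#' @export
print.pose_obs <- function(x, ...) {
  cat("<pose_obs>", x$model, " sigma =", format(x$sigma, digits = 4), "\n")
  invisible(x)
}

#' Simulate a batch of observations
#'
#' Vectorized variant of [simulate_observation()]: draws `n` ground-truth
#' rotations from `prior`, applies the model chain, and returns the flattened
#' observations as columns of a `d x n` matrix together with the truth.
#'
#' @inheritParams simulate_observation
#' @param n Number of observations.
#' @return A list with `Y` (`d x n` matrix), `g_true` (`3 x 3 x n` array, 3D
#'   models) or `k_true` (integer vector, polar), `model`, `sigma`, and the
#'   payload `dims`.
#' @export
simulate_batch <- function(V, prior = prior_haar(), sigma, model, n, seed = NULL) {
  model <- match.arg(model, c("no_projection_3d", "projection_2d", "polar_2d"))
  if (n < 0) stop("`n` must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (model == "polar_2d") {
    k <- sample.int(ncol(V), n, replace = TRUE) - 1L
    D <- length(V)
    Y <- matrix(0, D, n)
    for (i in seq_len(n)) Y[, i] <- as.numeric(unclass(rotate_polar(V, k[i])))
    Y <- Y + matrix(rnorm(D * n, sd = sigma), D, n)
    return(list(Y = Y, k_true = k, g_true = NULL, model = model,
                sigma = sigma, dims = dim(V)))
  }
  gs <- sample_prior(prior, max(n, 1L))
  if (n == 0L) gs <- gs[, , 0, drop = FALSE]
  # sampling matrix for active rotation is R^T
  Smat <- matrix(gs, 9L, n)[c(1, 4, 7, 2, 5, 8, 3, 6, 9), , drop = FALSE]
  X <- cpp_resample_batch(.strip(V), Smat)
  if (model == "projection_2d") {
    N <- dim(V)[1]
    X <- apply(X, 2L, function(col) rowSums(matrix(col, N * N, N)))
    if (n == 1L) X <- matrix(X, ncol = 1L)
    dims <- c(N, N)
  } else dims <- dim(V)
  Y <- X + matrix(rnorm(length(X), sd = sigma), nrow(X), ncol(X))
  list(Y = Y, g_true = gs, k_true = NULL, model = model, sigma = sigma,
       dims = dims)
}
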