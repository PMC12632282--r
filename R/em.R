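# Iterative structure recovery without projection: soft-assignment EM whose
# M-step is the MMSE-operator average, and the hard-assignment (MLE)
# counterpart. 3D volume and 2D polar variants.

#' EM configuration
#'
#' @param max_iter Maximum number of iterations (default 100).
#' @param tol Relative-change stopping threshold (default 1e-3): iteration
#'   stops once `||V_t - V_{t-1}|| / ||V_{t-1}|| < tol`.
#' @param assignment `"soft"` (posterior-weighted, EM proper) or `"hard"`
#'   (argmax node per observation).
#' @param sigma Noise standard deviation used in the E-step.
#' @param seed Optional integer seed (recorded; the iteration itself is
#'   deterministic given the inputs).
#' @return A list of class `em_config`.
#' @export
em_config <- function(max_iter = 100L, tol = 1e-3,
                      assignment = c("soft", "hard"), sigma, seed = NULL) {
  assignment <- match.arg(assignment)
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be positive", call. = FALSE)
  if (max_iter < 1) stop("`max_iter` must be >= 1", call. = FALSE)
  if (missing(sigma) || sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 assignment = assignment, sigma = sigma, seed = seed),
            class = "em_config")
}

# ---- E and M steps (3D) -----------------------------------------------------

#' EM expectation step
#'
#' For each observation `y_i`, computes the posterior weights over the grid
#' nodes, `p_i(l) propto w_l exp(-||y_i - g_l o V_hat||^2 / (2 sigma^2))`,
#' in the log domain with per-row max subtraction.
#'
#' @param V_hat Current volume estimate (a [vol3]).
#' @param Y Observations as a `d x M` matrix (columns = flattened volumes),
#'   or a list of `pose_obs`.
#' @param grid An [so3_grid].
#' @param sigma Noise standard deviation.
#' @return A list with `P` (`M x L` matrix of posterior weights, rows on the
#'   simplex), `loglik` (`L x M`), and `marginal_ll` (length `M`; the
#'   per-observation log marginal likelihood up to a shared constant).
#' @export
e_step <- function(V_hat, Y, grid, sigma) {
  if (is.list(Y) && is.null(dim(Y))) Y <- .as_batch(Y)$Y
  bank <- build_templates(V_hat, grid, "no_projection_3d")
  ll <- .log_likelihoods_batch(Y, bank, sigma)          # L x M
  lw <- ll + log(grid$weights)
  m <- apply(lw, 2L, max)
  W <- exp(sweep(lw, 2L, m))
  Z <- colSums(W)
  P <- t(sweep(W, 2L, Z, "/"))                          # M x L
  list(P = P, loglik = ll, marginal_ll = m + log(Z))
}

#' EM maximization steps
#'
#' `m_step_soft()` returns the posterior-weighted back-rotation average
#' `(1/M) sum_i sum_l p_i(l) (g_l)^-1 o y_i`: every observation aligned to
#' every node by the inverse node rotation, weighted by its posterior, then
#' averaged. This equals the average of the observations aligned by their
#' MMSE rotation *operators* (the operator form of the posterior mean), and
#' is the exact minimizer of the complete-data weighted squared loss.
#'
#' `m_step_hard()` aligns each observation only by the inverse of its argmax
#' (MLE) node and averages.
#'
#' @param Y Observations (`d x M` matrix or list of `pose_obs`).
#' @param P `M x L` posterior weight matrix from [e_step()].
#' @param grid An [so3_grid].
#' @param dims Volume dimensions (taken from `n^3 = d` when omitted).
#' @return A [vol3].
#' @export
m_step_soft <- function(Y, P, grid, dims = NULL) {
  if (is.list(Y) && is.null(dim(Y))) Y <- .as_batch(Y)$Y
  M <- ncol(Y)
  if (nrow(P) != M || ncol(P) != grid$L)
    stop("`P` must be M x L, matching observations and grid", call. = FALSE)
  n <- .cube_side(nrow(Y), dims)
  flat <- matrix(grid$rotations, 9L, grid$L)   # column-major R; sampling matrix for g^-1 is R itself
  acc <- array(0, c(n, n, n))
  for (i in seq_len(M)) {
    yi <- array(Y[, i], c(n, n, n))
    acc <- acc + cpp_resample_accum(yi, flat, P[i, ])
  }
  vol3(acc / M)
}

#' @rdname m_step_soft
#' @export
m_step_hard <- function(Y, P, grid, dims = NULL) {
  if (is.list(Y) && is.null(dim(Y))) Y <- .as_batch(Y)$Y
  M <- ncol(Y)
  if (nrow(P) != M || ncol(P) != grid$L)
    stop("`P` must be M x L, matching observations and grid", call. = FALSE)
  n <- .cube_side(nrow(Y), dims)
  ks <- max.col(P, ties.method = "first")
  flat <- matrix(grid$rotations, 9L, grid$L)
  acc <- array(0, c(n, n, n))
  for (i in seq_len(M)) {
    yi <- array(Y[, i], c(n, n, n))
    acc <- acc + cpp_resample(yi, flat[, ks[i]])
  }
  vol3(acc / M)
}

.cube_side <- function(d, dims = NULL) {
  if (!is.null(dims)) return(dims[1])
  n <- round(d^(1 / 3))
  if (n^3 != d) stop("observation length is not a cube; pass `dims`",
                     call. = FALSE)
  as.integer(n)
}

# ---- refinement loops -------------------------------------------------------

#' Iterative refinement without projection (3D)
#'
#' Alternates [e_step()] and the configured M-step from `V0` until the
#' relative L2 change of the volume estimate drops below `config$tol` or
#' `config$max_iter` is reached. Each iteration records the relative change,
#' the complete-data weighted squared loss, the marginal negative
#' log-likelihood (the quantity EM is guaranteed not to increase), and
#' Pearson correlations to optional truth/template references.
#'
#' @param V0 Initial volume (a [vol3]); for template-bias experiments this is
#'   the biased template.
#' @param Y Observations (`d x M` matrix or list of `pose_obs`).
#' @param grid An [so3_grid].
#' @param config An [em_config].
#' @param truth,template Optional reference [vol3]s for per-iteration PCC
#'   tracking (`template` defaults to `V0`).
#' @return An object of class `em_fit`: list with `V_hat` (final [vol3]),
#'   `trajectory` (tibble: `t`, `rel_change`, `objective`, `nll`,
#'   `pcc_truth`, `pcc_template`), `converged`, `iterations`, `config`.
#' @export
run_refinement <- function(V0, Y, grid, config, truth = NULL, template = V0) {
  stopifnot(inherits(V0, "vol3"), inherits(config, "em_config"))
  if (is.list(Y) && is.null(dim(Y))) Y <- .as_batch(Y)$Y
  V_hat <- V0
  M <- ncol(Y)
  traj <- vector("list", config$max_iter)
  converged <- FALSE
  P <- NULL
  for (t in seq_len(config$max_iter)) {
    es <- e_step(V_hat, Y, grid, config$sigma)
    P <- es$P
    V_new <- if (config$assignment == "soft") m_step_soft(Y, P, grid)
             else m_step_hard(Y, P, grid)
    if (!all(is.finite(V_new)))
      stop("non-finite volume estimate at iteration ", t, call. = FALSE)
    # complete-data loss sum_i sum_l p_il ||y_i - x_l(V_t)||^2, from loglik
    obj <- sum(P * t(-2 * config$sigma^2 * es$loglik))
    rel <- sqrt(sum((unclass(V_new) - unclass(V_hat))^2)) /
      max(sqrt(sum(unclass(V_hat)^2)), .Machine$double.eps)
    traj[[t]] <- tibble::tibble(
      t = t, rel_change = rel, objective = obj,
      nll = -sum(es$marginal_ll),
      pcc_truth = if (!is.null(truth)) .pcc(V_new, truth) else NA_real_,
      pcc_template = if (!is.null(template)) .pcc(V_new, template) else NA_real_)
    V_hat <- V_new
    if (rel < config$tol) { converged <- TRUE; break }
  }
  structure(list(V_hat = V_hat, trajectory = dplyr::bind_rows(traj),
                 converged = converged, iterations = sum(lengths(traj) > 0),
                 weights = P, config = config),
            class = "em_fit")
}

#' Iterative refinement on the polar grid (2D)
#'
#' The in-plane (SO(2)) variant of [run_refinement()]: the group action is an
#' exact cyclic shift of the angular axis, so alignment involves no
#' interpolation and EM monotonicity of the marginal likelihood is exact.
#' All `L_ang` rotations are scored against all observations with one matrix
#' product per iteration.
#'
#' @param img0 Initial [polar_img] (the template).
#' @param Y Observations as a `(d * L_ang) x M` matrix of flattened polar
#'   images, or a list of `pose_obs`.
#' @param config An [em_config].
#' @param truth,template Optional [polar_img] references for PCC tracking;
#'   PCC against each reference is maximized over the global cyclic-shift
#'   gauge.
#' @return An `em_fit` whose `V_hat` is a [polar_img].
#' @export
run_refinement_polar <- function(img0, Y, config, truth = NULL, template = img0) {
  stopifnot(inherits(img0, "polar_img"), inherits(config, "em_config"))
  if (is.list(Y) && is.null(dim(Y))) Y <- .as_batch(Y)$Y
  d <- nrow(img0); La <- ncol(img0)
  if (nrow(Y) != d * La) stop("observation rows must equal d * L_ang", call. = FALSE)
  M <- ncol(Y)
  V_hat <- unclass(img0)
  sq_y <- colSums(Y^2)
  traj <- vector("list", config$max_iter)
  converged <- FALSE
  P <- NULL
  for (t in seq_len(config$max_iter)) {
    S <- .polar_shift_bank(V_hat)                   # (d*La) x La
    cc <- crossprod(Y, S)                           # M x La
    sqn <- colSums(S^2)
    ll <- sweep(2 * cc, 2L, sqn, "-")
    ll <- sweep(ll, 1L, sq_y, "-") / (2 * config$sigma^2)   # M x La
    m <- apply(ll, 1L, max)
    W <- exp(sweep(ll, 1L, m))
    Z <- rowSums(W)
    P <- W / Z                                      # M x La (uniform weights)
    obj <- sum(P * (-2 * config$sigma^2 * ll))
    nll <- -sum(m + log(Z / La))
    V_new <- if (config$assignment == "soft") {
      B <- Y %*% P                       # one pass: column k = sum_i p_ik y_i
      acc <- matrix(0, d, La)
      for (k in seq_len(La) - 1L)
        acc <- acc + .shift_cols(matrix(B[, k + 1L], d, La), -k)
      acc / M
    } else {
      ks <- max.col(P, ties.method = "first") - 1L
      acc <- matrix(0, d, La)
      for (k in unique(ks)) {
        sel <- ks == k
        yk <- matrix(rowSums(Y[, sel, drop = FALSE]), d, La)
        acc <- acc + .shift_cols(yk, -k)
      }
      acc / M
    }
    if (!all(is.finite(V_new)))
      stop("non-finite image estimate at iteration ", t, call. = FALSE)
    rel <- sqrt(sum((V_new - V_hat)^2)) /
      max(sqrt(sum(V_hat^2)), .Machine$double.eps)
    traj[[t]] <- tibble::tibble(
      t = t, rel_change = rel, objective = obj, nll = nll,
      pcc_truth = if (!is.null(truth)) pcc_polar(polar_img(V_new), truth) else NA_real_,
      pcc_template = if (!is.null(template)) pcc_polar(polar_img(V_new), template) else NA_real_)
    V_hat <- V_new
    if (rel < config$tol) { converged <- TRUE; break }
  }
  structure(list(V_hat = polar_img(V_hat), trajectory = dplyr::bind_rows(traj),
                 converged = converged, iterations = sum(lengths(traj) > 0),
                 weights = P, config = config),
            class = "em_fit")
}

# columns of the bank are the La cyclic shifts of img (flattened)
.polar_shift_bank <- function(img) {
  d <- nrow(img); La <- ncol(img)
  S <- matrix(0, d * La, La)
  for (k in seq_len(La) - 1L)
    S[, k + 1L] <- as.numeric(.shift_cols(img, k))
  S
}

.shift_cols <- function(m, k) {
  La <- ncol(m)
  k <- ((k %% La) + La) %% La
  if (k == 0) return(m)
  idx <- ((seq_len(La) - 1L - k) %% La) + 1L
  m[, idx, drop = FALSE]
}

# ---- correlation helpers ----------------------------------------------------

#' Pearson correlations between reconstructions
#'
#' `pcc()` is the Pearson correlation of two mean-subtracted flattened
#' grids. `pcc_polar()` additionally maximizes over the global cyclic-shift
#' gauge of the polar angular axis, which a rotation-invariant reconstruction
#' cannot fix.
#'
#' @param a,b Same-shape payloads ([vol3], [polar_img], or arrays).
#' @return A correlation in `[-1, 1]`.
#' @export
pcc <- function(a, b) .pcc(a, b)

.pcc <- function(a, b) {
  x <- as.numeric(unclass(a)); y <- as.numeric(unclass(b))
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' @rdname pcc
#' @export
pcc_polar <- function(a, b) {
  am <- unclass(a); bm <- unclass(b)
  max(vapply(seq_len(ncol(am)) - 1L,
             function(k) .pcc(.shift_cols(am, k), bm), numeric(1)))
}

# ---- broom-style methods ----------------------------------------------------

#' @export
print.em_fit <- function(x, ...) {
  cat("<em_fit>", x$config$assignment, "assignment,", x$iterations,
      "iterations,", if (x$converged) "converged" else "max_iter reached", "\n")
  invisible(x)
}

#' Tidy an EM fit
#'
#' `tidy()` returns the per-iteration trajectory (relative change, objective,
#' negative log-likelihood, PCC tracks); `glance()` returns a one-row summary.
#'
#' @param x An `em_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.em_fit <- function(x, ...) x$trajectory

#' @rdname tidy.em_fit
#' @export
glance.em_fit <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  tibble::tibble(iterations = x$iterations, converged = x$converged,
                 assignment = x$config$assignment, sigma = x$config$sigma,
                 rel_change = last$rel_change, nll = last$nll,
                 pcc_truth = last$pcc_truth, pcc_template = last$pcc_template)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
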