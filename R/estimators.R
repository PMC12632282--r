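# MLE, MAP and MMSE orientation estimators over a shared template/posterior
# machinery. All likelihood arithmetic is done in the log domain with
# max-subtraction: at cryo-EM-like noise levels the unnormalized posterior
# weights underflow catastrophically in the linear domain.

# ---- template bank ----------------------------------------------------------

#' Build a template bank
#'
#' Precomputes the templates `x_l = Pi(g_l o V)` for every node of a rotation
#' grid: the rotated (and, for `projection_2d`, projected) reference against
#' which observations are matched. For the `polar_2d` model the templates are
#' the `L_ang` exact cyclic shifts of the reference polar image and `grid`
#' is ignored.
#'
#' @param V A [vol3] (3D models) or [polar_img] (polar model).
#' @param grid An [so3_grid] (ignored for `polar_2d`).
#' @param model Measurement model tag.
#' @param max_elements Memory guard: refuse banks with more than this many
#'   stored values (default `5e8`).
#' @return An object of class `template_bank`: list with `X` (`d x L` matrix,
#'   one template per column), `sq_norms`, `grid`, `model`, `dims`.
#' @export
build_templates <- function(V, grid = NULL, model,
                            max_elements = getOption("bayespose.max_bank_elements", 5e8)) {
  model <- match.arg(model, c("no_projection_3d", "projection_2d", "polar_2d"))
  if (model == "polar_2d") {
    if (!inherits(V, "polar_img"))
      stop("polar_2d model needs a polar image reference", call. = FALSE)
    La <- ncol(V)
    X <- matrix(0, length(V), La)
    for (k in seq_len(La) - 1L)
      X[, k + 1L] <- as.numeric(unclass(rotate_polar(V, k)))
    bank <- list(X = X, sq_norms = colSums(X^2), grid = NULL, model = model,
                 dims = dim(V), L = La)
    return(structure(bank, class = "template_bank"))
  }
  if (!inherits(V, "vol3")) stop(model, " model needs a volume", call. = FALSE)
  if (is.null(grid)) stop("3D models need a rotation grid", call. = FALSE)
  d <- if (model == "projection_2d") prod(dim(V)[1:2]) else length(V)
  if (as.double(d) * grid$L > max_elements)
    stop(sprintf(
      "template bank of %d x %d = %.2g values exceeds the memory budget (%.2g); lower L or raise `max_elements`",
      d, grid$L, as.double(d) * grid$L, max_elements), call. = FALSE)
  flat <- matrix(grid$rotations, 9L, grid$L)
  Smat <- flat[c(1, 4, 7, 2, 5, 8, 3, 6, 9), , drop = FALSE]  # R^T per node
  X <- cpp_resample_batch(.strip(V), Smat)
  dims <- dim(V)
  if (model == "projection_2d") {
    N <- dim(V)[1]
    X <- apply(X, 2L, function(col) rowSums(matrix(col, N * N, N)))
    dims <- c(N, N)
  }
  structure(list(X = X, sq_norms = colSums(X^2), grid = grid, model = model,
                 dims = dims, L = grid$L),
            class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat("<template_bank>", x$model, ":", nrow(x$X), "samples x", x$L,
      "templates\n")
  invisible(x)
}

# ---- likelihood and posterior ----------------------------------------------

.obs_vector <- function(y, bank) {
  v <- as.numeric(unclass(if (inherits(y, "pose_obs")) y$y else y))
  if (length(v) != nrow(bank$X))
    stop("observation layout does not match the template bank", call. = FALSE)
  v
}

#' Per-node log-likelihoods
#'
#' Returns `-||y - x_l||^2 / (2 sigma^2)` for every template, computed
#' through the inner-product expansion
#' `||y||^2 - 2 <y, x_l> + ||x_l||^2` with precomputed template norms.
#'
#' @param y A `pose_obs` (its `sigma` is used) or a numeric payload (then
#'   `sigma` must be given).
#' @param bank A [template_bank].
#' @param sigma Noise standard deviation (overrides the observation's).
#' @return Numeric vector of length `L`.
#' @export
log_likelihoods <- function(y, bank, sigma = NULL) {
  if (is.null(sigma)) {
    if (!inherits(y, "pose_obs"))
      stop("`sigma` is required when `y` is not a pose_obs", call. = FALSE)
    sigma <- y$sigma
  }
  v <- .obs_vector(y, bank)
  cc <- as.numeric(crossprod(bank$X, v))
  -(sum(v^2) - 2 * cc + bank$sq_norms) / (2 * sigma^2)
}

# batch version: Y is d x n; returns L x n matrix
.log_likelihoods_batch <- function(Y, bank, sigma) {
  cc <- crossprod(bank$X, Y)                       # L x n
  sq_y <- colSums(Y^2)
  ll <- sweep(2 * cc, 1L, bank$sq_norms, "-")
  ll <- sweep(ll, 2L, sq_y, "-")
  ll / (2 * sigma^2)
}

#' Posterior weights over grid nodes
#'
#' Forms the discrete posterior
#' `p(l) propto w_l * Lambda(g_l) * exp(loglik_l)`, normalized on the
#' simplex, in the log domain with max-subtraction. These weights are the
#' common intermediate of the MAP and MMSE estimators and of the EM E-step.
#'
#' @param loglik Numeric vector of per-node log-likelihoods.
#' @param grid The [so3_grid] the log-likelihoods were computed on.
#' @param prior An [so3_prior] (default uniform). On a Monte Carlo grid drawn
#'   from a prior (see [so3_grid_from_prior()]) keep this uniform: the prior
#'   is already encoded in the node distribution.
#' @return An object of class `so3_posterior`: list with `p`, `log_p`,
#'   `entropy` (nats), `argmax`, `tie` (logical).
#' @export
posterior_weights <- function(loglik, grid = NULL, prior = prior_haar()) {
  if (!all(is.finite(loglik) | loglik == -Inf))
    stop("log-likelihoods must be finite or -Inf", call. = FALSE)
  if (all(loglik == -Inf))
    stop("all log-likelihoods are -Inf", call. = FALSE)
  lp <- loglik
  if (!is.null(grid)) {
    lp <- lp + log(grid$weights)
    if (prior$kind != "haar_uniform")
      lp <- lp + prior_log_density_at_nodes(prior, grid)
  }
  m <- max(lp)
  w <- exp(lp - m)
  Z <- sum(w)
  p <- w / Z
  log_p <- lp - m - log(Z)
  amax <- which.max(p)
  tie <- sum(abs(p - p[amax]) < .TOL) > 1L
  ent <- -sum(ifelse(p > 0, p * log_p, 0))
  structure(list(p = p, log_p = log_p, entropy = ent,
                 argmax = amax, tie = tie),
            class = "so3_posterior")
}

#' @export
print.so3_posterior <- function(x, ...) {
  cat("<so3_posterior> L =", length(x$p), " max p =",
      format(x$p[x$argmax], digits = 4), " entropy =",
      format(x$entropy, digits = 4), "nats\n")
  invisible(x)
}

# ---- single-observation estimators -----------------------------------------

.estimate_result <- function(rotation, method, weights = NULL,
                             procrustes_gap = NA_real_, nonunique = FALSE,
                             node = NA_integer_) {
  structure(list(rotation = rotation, method = method, weights = weights,
                 procrustes_gap = procrustes_gap, nonunique = nonunique,
                 node = node),
            class = "pose_estimate")
}

#' @export
print.pose_estimate <- function(x, ...) {
  cat("<pose_estimate>", x$method,
      if (!is.na(x$node)) paste0("(node ", x$node, ")") else "",
      if (x$nonunique) "[non-unique]" else "", "\n")
  print(x$rotation)
  invisible(x)
}

#' Grid orientation estimators
#'
#' * `estimate_mle()` -- the maximum-likelihood (maximum cross-correlation)
#'   estimator: the grid node minimizing `||y - x_l||^2`. The noise level
#'   does not enter the argmin.
#' * `estimate_map()` -- the maximum-a-posteriori node: argmax of the
#'   posterior weights `w_l Lambda(g_l) exp(loglik_l)`. With a uniform prior
#'   and equal quadrature weights it coincides with the MLE node. Set
#'   `use_quadrature_weights = FALSE` for the pure prior-times-likelihood
#'   argmax.
#' * `estimate_mmse()` -- the Bayes estimator under squared chordal loss:
#'   the posterior-weighted mean of the node rotation matrices
#'   (`g_relax = sum_l p_l g_l`, a 3x3 matrix generally outside SO(3))
#'   projected back onto SO(3) by orthogonal Procrustes. The result carries
#'   the posterior, the Procrustes gap `||g_relax - g_MMSE||_F`, and a
#'   non-uniqueness flag for degenerate posterior means.
#'
#' Argmax/argmin ties are broken toward the lowest node index and flagged.
#'
#' @param y A `pose_obs`, or a numeric payload with `sigma` supplied.
#' @param bank A [template_bank] built on the grid to search.
#' @param prior An [so3_prior].
#' @param sigma Optional noise standard deviation override.
#' @param use_quadrature_weights Include `log w_l` in the MAP objective
#'   (default `TRUE`).
#' @return A `pose_estimate`: list with `rotation` ([rot3]), `method`,
#'   `weights`, `procrustes_gap`, `nonunique`, `node`.
#' @export
estimate_mle <- function(y, bank, sigma = NULL) {
  ll <- log_likelihoods(y, bank, sigma = sigma)
  k <- which.max(ll)
  tie <- sum(ll >= ll[k] - .TOL) > 1L
  .estimate_result(.node_rotation(bank, k), "mle", nonunique = tie, node = k)
}

#' @rdname estimate_mle
#' @export
estimate_map <- function(y, bank, prior = prior_haar(), sigma = NULL,
                         use_quadrature_weights = TRUE) {
  ll <- log_likelihoods(y, bank, sigma = sigma)
  grid <- if (use_quadrature_weights) bank$grid else NULL
  if (!use_quadrature_weights && !is.null(bank$grid) &&
      prior$kind != "haar_uniform")
    ll <- ll + prior_log_density_at_nodes(prior, bank$grid)
  pw <- posterior_weights(ll, grid = grid, prior = prior)
  .estimate_result(.node_rotation(bank, pw$argmax), "map", weights = pw,
                   nonunique = pw$tie, node = pw$argmax)
}

#' @rdname estimate_mle
#' @export
estimate_mmse <- function(y, bank, prior = prior_haar(), sigma = NULL) {
  ll <- log_likelihoods(y, bank, sigma = sigma)
  pw <- posterior_weights(ll, grid = bank$grid, prior = prior)
  if (bank$model == "polar_2d") {
    # SO(2): the posterior mean of 2x2 rotations is projected onto SO(2) by
    # the angle of the mean resultant vector
    La <- bank$L
    th <- 2 * pi * (seq_len(La) - 1L) / La
    zc <- sum(pw$p * cos(th)); zs <- sum(pw$p * sin(th))
    ang <- atan2(zs, zc) %% (2 * pi)
    est <- .estimate_result(NULL, "mmse", weights = pw,
                            procrustes_gap = 1 - sqrt(zc^2 + zs^2),
                            nonunique = (zc^2 + zs^2) < 1e-16,
                            node = pw$argmax)
    est$angle <- ang
    return(est)
  }
  flat <- matrix(bank$grid$rotations, 9L, bank$L)
  g_relax <- matrix(as.numeric(flat %*% pw$p), 3, 3)
  proj <- procrustes_project(g_relax)
  .estimate_result(proj, "mmse", weights = pw,
                   procrustes_gap = sqrt(sum((g_relax - unclass(proj))^2)),
                   nonunique = isTRUE(attr(proj, "nonunique")),
                   node = pw$argmax)
}

.node_rotation <- function(bank, k) {
  if (bank$model == "polar_2d")
    stop("polar banks index rotations by angle, not rot3 nodes", call. = FALSE)
  rot3(bank$grid$rotations[, , k], check = FALSE)
}

# ---- batch estimation -------------------------------------------------------

#' Estimate orientations for a batch of observations
#'
#' Maps the grid estimators over a batch and tabulates per-observation errors
#' against the ground truth when it is available. The computation is fully
#' vectorized: one cross-correlation matrix product per bank serves all
#' methods.
#'
#' @param observations A list of `pose_obs`, or a `simulate_batch()` result.
#' @param bank A [template_bank].
#' @param prior An [so3_prior] used by `map` and `mmse`.
#' @param methods Subset of `c("mle", "map", "mmse")`.
#' @param sigma Noise standard deviation (required if the batch does not
#'   carry one).
#' @return A tibble with one row per (observation, method): columns `obs`,
#'   `method`, `rotation` (list of [rot3]), `node`, `d_F`, `d_G`,
#'   `procrustes_gap`, `max_weight`, `entropy`, `status`.
#' @export
estimate_batch <- function(observations, bank, prior = prior_haar(),
                           methods = c("mle", "mmse"), sigma = NULL) {
  methods <- match.arg(methods, c("mle", "map", "mmse"), several.ok = TRUE)
  b <- .as_batch(observations)
  if (is.null(sigma)) sigma <- b$sigma
  n <- ncol(b$Y)
  if (n == 0L)
    return(tibble::tibble(obs = integer(), method = character(),
                          rotation = list(), node = integer(),
                          d_F = double(), d_G = double(),
                          procrustes_gap = double(), max_weight = double(),
                          entropy = double(), status = character()))
  ll <- .log_likelihoods_batch(b$Y, bank, sigma)    # L x n
  rows <- purrr::map(seq_len(n), function(i) {
    g_true <- if (!is.null(b$g_true)) rot3(b$g_true[, , i], check = FALSE)
  purrr::map(methods, function(m) {
      est <- tryCatch({
        switch(m,
          mle = {
            k <- which.max(ll[, i])
            .estimate_result(.node_rotation(bank, k), "mle", node = k)
          },
          map = {
            pw <- posterior_weights(ll[, i], grid = bank$grid, prior = prior)
            .estimate_result(.node_rotation(bank, pw$argmax), "map",
                             weights = pw, node = pw$argmax)
          },
          mmse = {
            pw <- posterior_weights(ll[, i], grid = bank$grid, prior = prior)
            flat <- matrix(bank$grid$rotations, 9L, bank$L)
            g_relax <- matrix(as.numeric(flat %*% pw$p), 3, 3)
            proj <- procrustes_project(g_relax)
            .estimate_result(proj, "mmse", weights = pw,
                             procrustes_gap = sqrt(sum((g_relax - unclass(proj))^2)),
                             nonunique = isTRUE(attr(proj, "nonunique")),
                             node = pw$argmax)
          })
      }, error = function(e) e)
      if (inherits(est, "error"))
        return(tibble::tibble(obs = i, method = m, rotation = list(NULL),
                              node = NA_integer_, d_F = NA_real_,
                              d_G = NA_real_, procrustes_gap = NA_real_,
                              max_weight = NA_real_, entropy = NA_real_,
                              status = conditionMessage(est)))
      tibble::tibble(
        obs = i, method = m, rotation = list(est$rotation),
        node = est$node,
        d_F = if (!is.null(g_true)) chordal_distance(g_true, est$rotation) else NA_real_,
        d_G = if (!is.null(g_true)) geodesic_distance(g_true, est$rotation) else NA_real_,
        procrustes_gap = est$procrustes_gap,
        max_weight = if (!is.null(est$weights)) max(est$weights$p) else NA_real_,
        entropy = if (!is.null(est$weights)) est$weights$entropy else NA_real_,
        status = "ok")
    })
  })
  dplyr::bind_rows(rows)
}

.as_batch <- function(observations) {
  if (is.list(observations) && !is.null(observations$Y)) return(observations)
  if (!length(observations))
    return(list(Y = matrix(0, 0, 0), g_true = NULL, sigma = NULL))
  stopifnot(all(vapply(observations, inherits, TRUE, "pose_obs")))
  Y <- vapply(observations, function(o) as.numeric(unclass(o$y)),
              numeric(length(observations[[1]]$y)))
  Y <- matrix(Y, ncol = length(observations))
  gt <- NULL
  if (!is.null(observations[[1]]$g_true)) {
    gt <- array(0, c(3, 3, length(observations)))
    for (i in seq_along(observations))
      gt[, , i] <- unclass(observations[[i]]$g_true)
  }
  list(Y = Y, g_true = gt, sigma = observations[[1]]$sigma,
       model = observations[[1]]$model)
}

# fast internal path used by the benchmark harness: takes Y (d x n), the
# truth rotations, a bank and a named list of (prior, bank) method specs.
# returns a tibble of per-trial errors for methods "mle" and "mmse".
.batch_errors <- function(Y, g_true, bank, sigma, methods = c("mle", "mmse"),
                          prior = prior_haar()) {
  ll <- .log_likelihoods_batch(Y, bank, sigma)
  n <- ncol(Y)
  gt_flat <- matrix(g_true, 9L, n)
  out <- list()
  if ("mle" %in% methods) {
    ks <- max.col(t(ll), ties.method = "first")
    est_flat <- matrix(bank$grid$rotations, 9L, bank$L)[, ks, drop = FALSE]
    out$mle <- .err_tbl("mle", est_flat, gt_flat)
  }
  if ("mmse" %in% methods || "map" %in% methods) {
    lw <- log(bank$grid$weights)
    lpri <- if (prior$kind == "haar_uniform") 0
            else prior_log_density_at_nodes(prior, bank$grid)
    lp <- ll + lw + lpri
    m <- apply(lp, 2L, max)
    P <- exp(sweep(lp, 2L, m))
    P <- sweep(P, 2L, colSums(P), "/")                 # L x n posterior
    if ("map" %in% methods) {
      ks <- max.col(t(P), ties.method = "first")
      est_flat <- matrix(bank$grid$rotations, 9L, bank$L)[, ks, drop = FALSE]
      out$map <- .err_tbl("map", est_flat, gt_flat)
    }
    if ("mmse" %in% methods) {
      flat <- matrix(bank$grid$rotations, 9L, bank$L)
      Grel <- flat %*% P                                # 9 x n
      est_flat <- apply(Grel, 2L, function(v)
        as.numeric(unclass(procrustes_project(matrix(v, 3, 3)))))
      out$mmse <- .err_tbl("mmse", est_flat, gt_flat)
    }
  }
  dplyr::bind_rows(out)
}

.err_tbl <- function(method, est_flat, gt_flat) {
  # d_F^2 = 6 - 2 tr(est gt^T); d_G = angle of est gt^-1
  tr <- colSums(est_flat * gt_flat)
  dF2 <- pmax(0, 6 - 2 * tr)
  tibble::tibble(trial = seq_len(ncol(gt_flat)), method = method,
                 d_F = sqrt(dF2), d_G = acos(.clamp1((tr - 1) / 2)))
}
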