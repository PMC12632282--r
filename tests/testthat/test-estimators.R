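# Template banks, posterior weights, and the MLE/MAP/MMSE estimators.

test_that("template banks reproduce the forward model node by node", {
  V <- fx_vol8()
  g <- grid_with_identity(20, seed = 31)
  bank <- build_templates(V, g, "no_projection_3d")
  expect_equal(bank$X[, 1], as.numeric(unclass(V)), tolerance = 1e-12)
  k <- 7L
  ref <- rotate_volume(V, rot3(g$rotations[, , k], check = FALSE))
  expect_equal(bank$X[, k], as.numeric(unclass(ref)), tolerance = 1e-12)
  expect_equal(bank$sq_norms, colSums(bank$X^2), tolerance = 1e-12)
  # spherically symmetric reference: all templates coincide
  shb <- build_templates(fx_shell16(), so3_grid(24), "no_projection_3d")
  base <- shb$X[, 1]
  worst <- max(apply(shb$X, 2, function(x) sqrt(sum((x - base)^2)) /
                       sqrt(sum(base^2))))
  expect_lt(worst, 1e-2)
  # polar banks are exact cyclic shifts
  img <- make_phantom_polar(24, 10, "blobs", seed = 9)
  pb <- build_templates(img, model = "polar_2d")
  for (k in 0:9)
    expect_identical(pb$X[, k + 1],
                     as.numeric(unclass(rotate_polar(img, k))))
  # memory guard
  expect_error(build_templates(fx_vol16(), so3_grid(300), "no_projection_3d",
                               max_elements = 1e4), "memory budget")
})

test_that("log-likelihoods match direct evaluation and rank the true node first", {
  V <- fx_vol8()
  g <- grid_with_identity(20, seed = 32)
  bank <- build_templates(V, g, "no_projection_3d")
  k <- 11L
  y <- bank$X[, k]
  ll <- log_likelihoods(y, bank, sigma = 0.3)
  expect_equal(which.max(ll), k)
  naive <- -apply(bank$X, 2, function(x) sum((y - x)^2)) / (2 * 0.3^2)
  expect_equal(ll, naive, tolerance = 1e-6)
  # sigma does not change the argmax
  expect_equal(which.max(log_likelihoods(y, bank, sigma = 7)), k)
  expect_error(log_likelihoods(y[-1], bank, sigma = 1), "layout")
})

test_that("posterior weights normalize, ignore constants, and sharpen as sigma drops", {
  g <- so3_grid(50)
  L <- g$L
  pw <- posterior_weights(rep(-3, L), grid = g)
  expect_equal(pw$p, rep(1 / L, L), tolerance = 1e-12)
  expect_equal(sum(pw$p), 1, tolerance = 1e-12)
  expect_equal(pw$p, exp(pw$log_p), tolerance = 1e-10)
  set.seed(33)
  ll <- rnorm(L)
  expect_equal(posterior_weights(ll, grid = g)$p,
               posterior_weights(ll + 1234.5, grid = g)$p, tolerance = 1e-12)
  # scaling log-likelihoods up (sigma -> 0) gives a one-hot posterior
  sharp <- posterior_weights(ll * 1e6, grid = g)
  expect_equal(max(sharp$p), 1, tolerance = 1e-12)
  expect_equal(sharp$argmax, which.max(ll))
  expect_lt(sharp$entropy, 1e-6)
  expect_error(posterior_weights(rep(-Inf, 5)), "-Inf")
  # no overflow at extreme noise levels on unit-power signals
  V <- fx_vol8()
  bank <- build_templates(V, so3_grid(20), "no_projection_3d")
  llx <- log_likelihoods(as.numeric(unclass(V)), bank, sigma = 1e-6)
  pw2 <- posterior_weights(llx, grid = bank$grid)
  expect_true(all(is.finite(pw2$p)))
  expect_equal(sum(pw2$p), 1, tolerance = 1e-12)
})

test_that("MLE recovers on-grid truth exactly and off-grid truth to the nearest node", {
  V <- fx_vol16()
  bank <- fx_bank300()
  g <- bank$grid
  k <- 123L
  obs <- structure(list(y = vol3(array(bank$X[, k], dim(V))), sigma = 0.01,
                        model = "no_projection_3d", g_true = NULL,
                        k_true = NULL), class = "pose_obs")
  expect_equal(estimate_mle(obs, bank)$node, k)
  # off-grid, zero noise: brute-force nearest node in geodesic distance
  set.seed(34)
  for (i in 1:5) {
    gt <- rand_rot()
    y <- as.numeric(unclass(rotate_volume(V, gt)))
    est <- estimate_mle(y, bank, sigma = 1)
    near <- which.min(geodesic_all(gt, g$rotations))
    expect_equal(est$node, near)
  }
})

test_that("MAP equals MLE under a uniform prior and tracks the prior when it dominates", {
  V <- fx_vol16()
  bank <- fx_bank300()
  sig <- sigma_for_snr(V, 0.1)
  b <- simulate_batch(V, prior_haar(), sig, "no_projection_3d", 20, seed = 35)
  for (i in 1:20) {
    y <- b$Y[, i]
    expect_equal(estimate_map(y, bank, prior_haar(), sigma = sig)$node,
                 estimate_mle(y, bank, sigma = sig)$node)
  }
  # exhaustive log-posterior oracle under a non-uniform prior
  pr <- prior_igso3(0.5)
  lpri <- prior_log_density_at_nodes(pr, bank$grid)
  for (i in 1:5) {
    y <- b$Y[, i]
    ll <- log_likelihoods(y, bank, sigma = sig)
    oracle <- which.max(ll + lpri + log(bank$grid$weights))
    expect_equal(estimate_map(y, bank, pr, sigma = sig)$node, oracle)
  }
  # overwhelming prior + huge noise: the node nearest the identity wins
  est <- estimate_map(b$Y[, 1], bank, prior_igso3(0.1), sigma = 1e4)
  near_id <- which.min(rot_angles(bank$grid$rotations))
  expect_equal(est$node, near_id)
})

test_that("MMSE is the Procrustes of the posterior rotation mean", {
  V <- fx_vol16()
  bank <- fx_bank300()
  # one-hot posterior returns that node exactly
  k <- 200L
  y <- bank$X[, k]
  est <- estimate_mmse(y, bank, sigma = sigma_for_snr(V, 1e4))
  expect_lt(geodesic_distance(est$rotation,
                              rot3(bank$grid$rotations[, , k], check = FALSE)),
            1e-6)
  expect_lt(est$procrustes_gap, 1e-3)
  # half/half weights on a symmetric pair about z average to the identity
  th <- 1.1
  A <- 0.5 * unclass(rot3_axis_angle(c(0, 0, 1), th)) +
       0.5 * unclass(rot3_axis_angle(c(0, 0, 1), 2 * pi - th))
  expect_lt(max(abs(unclass(procrustes_project(A)) - diag(3))), 1e-10)
  # posterior-risk oracle: no Haar candidate beats the Procrustes solution
  sig <- sigma_for_snr(V, 0.05)
  b <- simulate_batch(V, prior_haar(), sig, "no_projection_3d", 5, seed = 36)
  cand <- sample_haar(1e4, seed = 37)
  cflat <- matrix(cand, 9L, 1e4)
  for (i in 1:5) {
    est <- estimate_mmse(b$Y[, i], bank, sigma = sig)
    flat <- matrix(bank$grid$rotations, 9L, bank$L)
    A <- matrix(as.numeric(flat %*% est$weights$p), 3, 3)
    risk_est <- 6 - 2 * sum(unclass(est$rotation) * A)
    risk_cand <- 6 - 2 * as.numeric(as.numeric(A) %*% cflat)
    expect_lte(risk_est, min(risk_cand) + 1e-9)
  }
})

test_that("polar MMSE projects the circular posterior mean onto SO(2)", {
  img <- make_phantom_polar(60, 12, "blobs", seed = 10)
  bank <- build_templates(img, model = "polar_2d")
  k <- 4L
  y <- as.numeric(unclass(rotate_polar(img, k)))
  est <- estimate_mmse(y, bank, sigma = sigma_for_snr(img, 100))
  expect_equal(est$angle, 2 * pi * k / 12, tolerance = 1e-3)
  expect_equal(est$node, k + 1L)
})

test_that("batch estimation reproduces single calls and handles the empty batch", {
  V <- fx_vol16()
  bank <- fx_bank300()
  empty <- estimate_batch(list(), bank)
  expect_s3_class(empty, "tbl_df")
  expect_equal(nrow(empty), 0L)
  # zero-noise on-grid observations: zero error for every method
  ks <- c(5L, 50L, 250L)
  obs <- list(Y = bank$X[, ks],
              g_true = bank$grid$rotations[, , ks],
              sigma = sigma_for_snr(V, 1e6), model = "no_projection_3d")
  tb <- estimate_batch(obs, bank, methods = c("mle", "map", "mmse"))
  expect_equal(nrow(tb), 9L)
  expect_true(all(tb$status == "ok"))
  expect_lt(max(tb$d_G), 1e-6)
  # batch rows agree with the single-observation API
  sig <- sigma_for_snr(V, 0.1)
  b <- simulate_batch(V, prior_haar(), sig, "no_projection_3d", 5, seed = 38)
  tb2 <- estimate_batch(b, bank, methods = "mmse")
  for (i in 1:5) {
    single <- estimate_mmse(b$Y[, i], bank, sigma = sig)
    expect_lt(geodesic_distance(tb2$rotation[[i]], single$rotation), 1e-6)
    expect_equal(tb2$d_G[i],
                 geodesic_distance(rot3(b$g_true[, , i], check = FALSE),
                                   single$rotation), tolerance = 1e-6)
  }
})
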