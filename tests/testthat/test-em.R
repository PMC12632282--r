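# Soft/hard-assignment refinement: E-step, M-step identities, and the
# refinement loops.

test_that("E-step weights are simplex rows matching naive evaluation", {
  V <- fx_vol8()
  g <- grid_with_identity(20, seed = 40)
  sig <- sigma_for_snr(V, 0.5)
  b <- simulate_batch(V, prior_haar(), sig, "no_projection_3d", 6, seed = 41)
  es <- e_step(V, b$Y, g, sig)
  expect_equal(rowSums(es$P), rep(1, 6), tolerance = 1e-12)
  # naive per-node evaluation
  for (i in 1:3) {
    lognum <- vapply(seq_len(g$L), function(l) {
      xl <- unclass(rotate_volume(V, rot3(g$rotations[, , l], check = FALSE)))
      log(g$weights[l]) - sum((b$Y[, i] - as.numeric(xl))^2) / (2 * sig^2)
    }, numeric(1))
    p <- exp(lognum - max(lognum)); p <- p / sum(p)
    expect_equal(es$P[i, ], p, tolerance = 1e-8)
  }
  # sigma -> 0 with an on-grid observation: one-hot at the generating node
  k <- 9L
  yk <- as.numeric(unclass(rotate_volume(V, rot3(g$rotations[, , k],
                                                 check = FALSE))))
  es0 <- e_step(V, matrix(yk, ncol = 1), g, sigma = 1e-4)
  expect_equal(which.max(es0$P[1, ]), k)
  expect_gt(es0$P[1, k], 1 - 1e-8)
})

test_that("soft M-step equals the posterior-weighted back-rotation double loop", {
  V <- fx_vol8()
  g <- grid_with_identity(50, seed = 42)
  sig <- sigma_for_snr(V, 0.3)
  b <- simulate_batch(V, prior_haar(), sig, "no_projection_3d", 10, seed = 43)
  es <- e_step(V, b$Y, g, sig)
  fast <- m_step_soft(b$Y, es$P, g)
  naive <- array(0, dim(V))
  for (i in 1:10) for (l in seq_len(g$L)) {
    gl <- rot3(g$rotations[, , l], check = FALSE)
    naive <- naive + es$P[i, l] *
      unclass(rotate_volume(vol3(array(b$Y[, i], dim(V))), rot3_invert(gl)))
  }
  expect_lt(max(abs(unclass(fast) - naive / 10)), 1e-8)
  # one observation with a one-hot posterior: exactly the back-rotated copy
  P1 <- matrix(0, 1, g$L); P1[1, 17] <- 1
  m1 <- m_step_soft(b$Y[, 1, drop = FALSE], P1, g)
  ref <- rotate_volume(vol3(array(b$Y[, 1], dim(V))),
                       rot3_invert(rot3(g$rotations[, , 17], check = FALSE)))
  expect_lt(max(abs(unclass(m1) - unclass(ref))), 1e-12)
  expect_error(m_step_soft(b$Y, es$P[1:3, ], g), "M x L")
})

test_that("hard M-step recovers on-grid observations and deviates when posteriors are diffuse", {
  # recovery is exact up to interpolation; measured on a phantom smooth at
  # the voxel scale (feature widths of 3.5-4 voxels) where the resampling
  # error sits below 2%
  n <- 24; ax <- seq_len(n) - 1 - (n - 1) / 2
  blob <- function(ctr, s)
    exp(-outer(outer((ax - ctr[1])^2, (ax - ctr[2])^2, "+"),
               (ax - ctr[3])^2, "+") / (2 * s^2))
  V <- vol3(blob(c(3, -2, 1), 3.5) + 0.7 * blob(c(-3, 2, -1), 4))
  g <- grid_with_identity(20, seed = 44)
  k <- 13L
  y <- as.numeric(unclass(rotate_volume(V, rot3(g$rotations[, , k],
                                                check = FALSE))))
  P <- matrix(0, 1, g$L); P[1, k] <- 1
  rec <- m_step_hard(matrix(y, ncol = 1), P, g)
  expect_lt(rel_l2(rec, V), 2e-2)
  # one-hot posteriors: soft and hard agree exactly
  expect_lt(max(abs(unclass(m_step_soft(matrix(y, ncol = 1), P, g)) -
                      unclass(rec))), 1e-12)
  # diffuse posteriors at low SNR: the two updates genuinely differ
  V16 <- fx_vol16()
  sig <- sigma_for_snr(V16, 0.005)
  b <- simulate_batch(V16, prior_haar(), sig, "no_projection_3d", 5, seed = 45)
  es <- e_step(V16, b$Y, grid_with_identity(20, seed = 44), sig)
  expect_gt(rel_l2(m_step_soft(b$Y, es$P, grid_with_identity(20, seed = 44)),
                   m_step_hard(b$Y, es$P, grid_with_identity(20, seed = 44))),
            0)
})

test_that("spherically symmetric data pass through the soft M-step unchanged", {
  sh <- fx_shell16()
  g <- so3_grid(30)
  M <- 4
  Y <- matrix(rep(as.numeric(unclass(sh)), M), ncol = M)
  P <- matrix(1 / g$L, M, g$L)
  expect_lt(rel_l2(m_step_soft(Y, P, g), sh), 2e-2)
})

test_that("3D refinement converges immediately on clean data from the truth", {
  V <- fx_vol8()
  g <- grid_with_identity(20, seed = 46)
  b <- simulate_batch(V, prior_haar(), 1e-6, "no_projection_3d", 5, seed = 47)
  # observations generated exactly at grid nodes so alignment is exact
  ks <- c(2L, 5L, 9L, 12L, 20L)
  Y <- vapply(ks, function(k)
    as.numeric(unclass(rotate_volume(V, rot3(g$rotations[, , k],
                                             check = FALSE)))),
    numeric(length(V)))
  fit <- run_refinement(V, Y, g, em_config(sigma = 0.01), truth = V)
  # the first M-step pays one interpolation pass; the assignments are already
  # exact, so the second iteration reproduces the first update and stops
  expect_true(fit$converged)
  expect_lte(fit$iterations, 2L)
  expect_gt(min(fit$trajectory$pcc_truth), 0.99)
})

test_that("em_config carries the documented defaults and validates inputs", {
  cfg <- em_config(sigma = 1)
  expect_equal(cfg$max_iter, 100L)
  expect_equal(cfg$tol, 1e-3)
  expect_equal(cfg$assignment, "soft")
  expect_error(em_config(tol = -1, sigma = 1), "positive")
  expect_error(em_config(max_iter = 0, sigma = 1), "max_iter")
  expect_error(em_config(sigma = 0), "sigma")
})

test_that("polar refinement: exact recovery, gauge equivariance, and monotone NLL", {
  img <- make_phantom_polar(40, 12, "blobs", seed = 11)
  d <- 40; La <- 12; M <- 30
  set.seed(48)
  ks <- sample.int(La, M, replace = TRUE) - 1L
  clean <- vapply(ks, function(k) as.numeric(unclass(rotate_polar(img, k))),
                  numeric(d * La))
  # zero noise: exact recovery up to the global cyclic-shift gauge
  fit0 <- run_refinement_polar(img, clean + 1e-9 * matrix(rnorm(d * La * M),
                                                          d * La, M),
                               em_config(sigma = 1e-3), truth = img)
  expect_gt(pcc_polar(fit0$V_hat, img), 1 - 1e-6)
  # noisy soft run: the marginal NLL never increases (exact EM guarantee
  # for the permutation action)
  sig <- sigma_for_snr(img, 0.2)
  Y <- clean + matrix(rnorm(d * La * M, sd = sig), d * La, M)
  tmpl <- make_phantom_polar(40, 12, "blobs", seed = 12)
  fit <- run_refinement_polar(tmpl, Y,
                              em_config(max_iter = 40, tol = 1e-10,
                                        assignment = "soft", sigma = sig),
                              truth = img)
  nll <- tidy(fit)$nll
  expect_true(all(diff(nll) <= 1e-8 * pmax(abs(nll[-length(nll)]), 1)))
  # gauge equivariance: shifting template and observations shifts the output
  shift <- 5L
  Ys <- apply(Y, 2, function(y)
    as.numeric(unclass(rotate_polar(polar_img(matrix(y, d, La)), shift))))
  fit_s <- run_refinement_polar(rotate_polar(tmpl, shift), Ys,
                                em_config(max_iter = 40, tol = 1e-10,
                                          assignment = "soft", sigma = sig))
  expect_lt(max(abs(unclass(rotate_polar(fit$V_hat, shift)) -
                      unclass(fit_s$V_hat))), 1e-8)
})

test_that("soft and hard polar refinements coincide at high SNR", {
  img <- make_phantom_polar(40, 12, "blobs", seed = 13)
  d <- 40; La <- 12; M <- 40
  sig <- sigma_for_snr(img, 1e3)
  set.seed(49)
  ks <- sample.int(La, M, replace = TRUE) - 1L
  Y <- vapply(ks, function(k) as.numeric(unclass(rotate_polar(img, k))),
              numeric(d * La)) + matrix(rnorm(d * La * M, sd = sig), d * La, M)
  tmpl <- make_phantom_polar(40, 12, "blobs", seed = 14)
  fs <- run_refinement_polar(tmpl, Y, em_config(sigma = sig,
                                                assignment = "soft"))
  fh <- run_refinement_polar(tmpl, Y, em_config(sigma = sig,
                                                assignment = "hard"))
  expect_gt(pcc_polar(fs$V_hat, fh$V_hat), 0.999)
})

test_that("tidy and glance summarize fits as tibbles", {
  img <- make_phantom_polar(20, 8, "blobs", seed = 15)
  set.seed(50)
  Y <- matrix(rnorm(20 * 8 * 10), 160, 10)
  fit <- run_refinement_polar(img, Y, em_config(max_iter = 5, sigma = 1),
                              truth = img)
  tr <- tidy(fit)
  expect_s3_class(tr, "tbl_df")
  expect_true(all(c("t", "rel_change", "objective", "nll", "pcc_truth",
                    "pcc_template") %in% names(tr)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$iterations, fit$iterations)
})
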