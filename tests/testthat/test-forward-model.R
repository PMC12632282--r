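# Measurement operators: rotation, projection, polar shift, noise, SNR.

test_that("volume rotation honors identity, symmetry and composition", {
  V <- fx_vol16()
  expect_identical(unclass(rotate_volume(V, rot3_identity())), unclass(V))
  sh <- fx_shell16()
  g <- rot3_axis_angle(c(1, 1, 0) / sqrt(2), 0.7)
  expect_lt(rel_l2(rotate_volume(sh, g), sh), 1e-2)
  # composition up to double-interpolation error, on a smooth phantom
  set.seed(20)
  g1 <- rand_rot(); g2 <- rand_rot()
  Vs <- make_phantom(24, "band_limited", seed = 6)
  expect_lt(rel_l2(rotate_volume(rotate_volume(Vs, g1), g2),
                   rotate_volume(Vs, rot3_compose(g2, g1))), 5e-2)
  # energy is conserved to interpolation tolerance
  expect_lt(abs(sum(unclass(rotate_volume(Vs, g1))^2) /
                  sum(unclass(Vs)^2) - 1), 0.02)
  Vp <- make_phantom(24, "gaussian_blobs", seed = 6)
  expect_lt(abs(sum(unclass(rotate_volume(Vp, g1))) / sum(unclass(Vp)) - 1),
            0.01)
})

test_that("rotation and projection are linear in the signal", {
  V1 <- fx_vol16()
  V2 <- make_phantom(16, "gaussian_blobs", seed = 6)
  g <- rand_rot(seed = 21)
  lhs <- rotate_volume(vol3(2 * unclass(V1) - 3 * unclass(V2)), g)
  rhs <- 2 * unclass(rotate_volume(V1, g)) - 3 * unclass(rotate_volume(V2, g))
  expect_lt(max(abs(unclass(lhs) - rhs)), 1e-8)
  expect_lt(max(abs(project_volume(vol3(2 * unclass(V1) - 3 * unclass(V2))) -
                      (2 * project_volume(V1) - 3 * project_volume(V2)))),
            1e-8)
})

test_that("projection conserves mass and respects spherical symmetry", {
  V <- fx_vol16()
  expect_equal(sum(project_volume(V)), sum(unclass(V)), tolerance = 1e-12)
  sh <- fx_shell16()
  p <- project_volume(sh)
  # radial symmetry: pixels at identical radius carry identical values,
  # since the phantom depends on x^2 + y^2 + z^2 only and Pi sums over z
  n <- nrow(p); ax <- seq_len(n) - 1 - (n - 1) / 2
  r2 <- outer(ax^2, ax^2, "+")
  ring_means <- stats::ave(as.numeric(p), factor(round(as.numeric(r2), 9)))
  expect_lt(stats::var(as.numeric(p) - ring_means), 1e-3 * mean(p^2))
  # projection of a rotated spherically symmetric volume is unchanged
  g <- rand_rot(seed = 22)
  expect_lt(rel_l2(project_volume(rotate_volume(sh, g)), p), 1e-2)
})

test_that("polar rotation is an exact cyclic group action", {
  img <- make_phantom_polar(24, 10, "blobs", seed = 7)
  expect_identical(unclass(rotate_polar(img, 0)), unclass(img))
  expect_identical(unclass(rotate_polar(img, 10)), unclass(img))
  expect_identical(unclass(rotate_polar(img, -3)),
                   unclass(rotate_polar(img, 7)))
  r1 <- rotate_polar(rotate_polar(img, 4), 5)
  expect_identical(unclass(r1), unclass(rotate_polar(img, 9)))
  expect_identical(sum(unclass(rotate_polar(img, 3))^2), sum(unclass(img)^2))
  expect_error(rotate_polar(fx_vol16(), 1), "polar")
})

test_that("noise injection has the right moments and is reproducible", {
  V <- fx_vol16()
  y1 <- add_noise(V, 0.5, seed = 23)
  y2 <- add_noise(V, 0.5, seed = 23)
  expect_identical(unclass(y1), unclass(y2))
  resid <- as.numeric(unclass(y1)) - as.numeric(unclass(V))
  expect_lt(abs(stats::var(resid) / 0.25 - 1), 0.05)
  expect_lt(max(abs(unclass(add_noise(V, 1e-12, seed = 24)) - unclass(V))),
            1e-10)
  expect_error(add_noise(V, 0), "positive")
})

test_that("SNR conventions invert each other", {
  V <- fx_vol16()
  expect_equal(snr_of(V, 2), snr_of(V, 1) / 4, tolerance = 1e-12)
  expect_equal(snr_of(V, sigma_for_snr(V, 0.37)), 0.37, tolerance = 1e-12)
  expect_equal(snr_of(vol3(array(1, c(4, 4, 4))), 1), 1, tolerance = 1e-12)
  expect_error(snr_of(vol3(array(0, c(4, 4, 4))), 1), "zero signal")
})

test_that("observation simulation applies the model chain and stores truth", {
  V <- fx_vol16()
  o <- simulate_observation(V, prior_haar(), sigma = 1e-9,
                            model = "no_projection_3d", seed = 25)
  expect_lt(rel_l2(o$y, rotate_volume(V, o$g_true)), 1e-6)
  o2 <- simulate_observation(V, prior_haar(), sigma = 0.5,
                             model = "projection_2d", seed = 26)
  expect_equal(dim(o2$y), c(16L, 16L))
  img <- make_phantom_polar(24, 10, "blobs", seed = 8)
  o3 <- simulate_observation(img, sigma = 0.5, model = "polar_2d", seed = 27)
  expect_true(o3$k_true %in% 0:9)
  expect_error(simulate_observation(img, sigma = 1, model = "no_projection_3d"),
               "volume")
  # haar-drawn true rotations have the haar angle law
  b <- simulate_batch(fx_vol8(), prior_haar(), 1, "no_projection_3d", 2000,
                      seed = 28)
  ks <- suppressWarnings(
    stats::ks.test(rot_angles(b$g_true), function(q) (q - sin(q)) / pi))
  expect_gt(ks$p.value, 0.01)
})

test_that("batch simulation agrees with the single-observation path", {
  V <- fx_vol8()
  b <- simulate_batch(V, prior_haar(), 1e-9, "no_projection_3d", 3, seed = 29)
  for (i in 1:3) {
    ref <- rotate_volume(V, rot3(b$g_true[, , i], check = FALSE))
    expect_lt(rel_l2(array(b$Y[, i], dim(V)), ref), 1e-6)
  }
  bp <- simulate_batch(V, prior_haar(), 0.5, "projection_2d", 4, seed = 30)
  expect_equal(nrow(bp$Y), 64L)
})
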