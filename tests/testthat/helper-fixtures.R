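# Shared fixtures, built in code and cached per test run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

fx_vol16 <- function() fixture("vol16", function()
  make_phantom(16, "band_limited", seed = 3))

fx_vol8 <- function() fixture("vol8", function()
  make_phantom(8, "band_limited", seed = 4))

fx_shell16 <- function() fixture("shell16", function()
  make_phantom(16, "spherical_shell"))

fx_grid300 <- function() fixture("grid300", function() so3_grid(300))

fx_bank300 <- function() fixture("bank300", function()
  build_templates(fx_vol16(), fx_grid300(), "no_projection_3d"))

# random rotations as rot3 objects
rand_rot <- function(seed = NULL) {
  g <- sample_haar(1, seed = seed)
  rot3(g[, , 1], check = FALSE)
}

# angles of a 3 x 3 x n rotation array
rot_angles <- function(rots) {
  flat <- matrix(rots, 9L, dim(rots)[3])
  acos(pmin(1, pmax(-1, (flat[1, ] + flat[5, ] + flat[9, ] - 1) / 2)))
}

rel_l2 <- function(a, b) {
  a <- as.numeric(unclass(a)); b <- as.numeric(unclass(b))
  sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
}

geodesic_all <- function(R, rots) {
  vapply(seq_len(dim(rots)[3]),
         function(i) geodesic_distance(R, rot3(rots[, , i], check = FALSE)),
         numeric(1))
}

# a grid whose first node is exactly the identity (handy for template tests)
grid_with_identity <- function(L = 20, seed = 5) {
  g <- so3_grid_from_prior(prior_haar(), L, seed = seed)
  g$rotations[, , 1] <- diag(3)
  g
}
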