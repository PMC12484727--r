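test_that("simulated signals are deterministic and carry planted truth", {
  s1 <- simulate_bold(12, 600, K_states = 4, noise_sd = 0.1, seed = 5)
  s2 <- simulate_bold(12, 600, K_states = 4, noise_sd = 0.1, seed = 5)
  expect_identical(s1$signals, s2$signals)
  expect_identical(dim(s1$signals), c(12L, 600L))
  expect_identical(length(s1$planted_truth$state), 600L)
  expect_equal(rowSums(s1$planted_truth$patterns^2), rep(1, 4))
  expect_error(simulate_bold(1, 600), "n_regions")
  expect_error(simulate_bold(12, 600, K_states = 1), "K_states")
})

test_that("noise-free phase structure matches the construction", {
  interior <- 51:750
  # timeline pinned to the global state: all pairwise differences ~ 0
  s1 <- simulate_bold(8, 800, K_states = 3, noise_sd = 0, seed = 2,
                      state_probs = c(1, 0, 0))
  ph1 <- instantaneous_phase(s1)
  dphi <- apply(ph1[, interior], 2, function(x)
    max(abs(Arg(exp(1i * (x - x[1]))))))
  expect_lt(max(dphi), 0.05)
  # recovered phase tracks the planted carrier away from edges
  carrier <- 2 * pi * s1$planted_truth$carrier_freq * (seq_len(800) - 1)
  err <- abs(Arg(exp(1i * (ph1[1, interior] - carrier[interior]))))
  expect_lt(max(err), 0.05)
  # timeline pinned to an anti-phase state: members vs complement ~ pi
  s2 <- simulate_bold(8, 800, K_states = 3, noise_sd = 0, seed = 2,
                      state_probs = c(0, 1, 0))
  ph2 <- instantaneous_phase(s2)
  members <- which(s2$planted_truth$phase_offsets[2, ] > 0)
  gap <- abs(Arg(exp(1i * (ph2[members[1], interior] -
                           ph2[setdiff(1:8, members)[1], interior]))))
  expect_gt(min(gap), pi - 0.1)
})

test_that("instantaneous phase of pure tones behaves like the analytic
           signal", {
  n <- 500; f <- 0.05              # integer number of periods: no leakage
  t_idx <- 0:(n - 1)
  ph <- instantaneous_phase(rbind(cos(2 * pi * f * t_idx),
                                  sin(2 * pi * f * t_idx)))
  interior <- 30:(n - 30)
  # cosine phase advances linearly at 2 pi f per sample
  slopes <- Arg(exp(1i * diff(ph[1, interior])))
  expect_lt(max(abs(slopes - 2 * pi * f)), 1e-6)
  # sine lags cosine by pi/2
  lag <- Arg(exp(1i * (ph[1, interior] - ph[2, interior])))
  expect_lt(max(abs(lag - pi / 2)), 1e-6)
  expect_error(instantaneous_phase(rbind(rep(1, 64))), "constant")
})

test_that("leading eigenvector: rank-one cases, sign convention and global
           phase-shift invariance", {
  # all phases equal: A is all ones, leading eigenvalue n, uniform vector
  ph <- matrix(0.7, 6, 3)
  ev <- leading_eigenvector_series(ph)
  expect_equal(abs(ev), matrix(1 / sqrt(6), 3, 6), tolerance = 1e-12)
  expect_true(all(rowSums(ev < 0) >= 3))
  # two anti-phase blocks: constant within blocks, opposite signs
  theta <- c(rep(0, 4), rep(pi, 3))
  evb <- leading_eigenvector_series(matrix(theta, 7, 1))
  # oracle: dense eigensolve of the explicit cosine matrix
  A <- cos(outer(theta, theta, `-`))
  v_or <- eigen(A, symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(as.vector(evb)), abs(v_or), tolerance = 1e-10)
  expect_lt(max(abs(evb[1, 1:4] - evb[1, 1])), 1e-10)
  expect_lt(max(abs(evb[1, 5:7] - evb[1, 5])), 1e-10)
  expect_lt(evb[1, 1] * evb[1, 5], 0)
  # adding a constant to all phases leaves the eigenvector unchanged
  evs <- leading_eigenvector_series(matrix(theta + 1.234, 7, 1))
  expect_equal(evs, evb, tolerance = 1e-10)
})

test_that("clustering recovers planted states and normalizes centroids", {
  s <- simulate_bold(10, 1200, K_states = 4, noise_sd = 0, seed = 9)
  ev <- leading_eigenvector_series(instantaneous_phase(s))
  em <- cluster_modes(ev, K = 4, seed = 9)
  expect_equal(unname(rowSums(em$centroids^2)), rep(1, 4))
  expect_equal(sum(em$occupancy), 1)
  mt <- match_eigenmodes_to_empirical(s$planted_truth$patterns, em)
  expect_identical(nrow(mt$best_match), 4L)
  expect_true(all(mt$best_match$similarity > 0.99))
  expect_false(any(duplicated(mt$best_match$empirical)))
})

test_that("K = 1 centroid equals the normalized mean vector", {
  s <- simulate_bold(8, 600, K_states = 3, noise_sd = 0.3, seed = 4)
  ev <- leading_eigenvector_series(instantaneous_phase(s))
  em <- cluster_modes(ev, K = 1, seed = 1)
  mu <- colMeans(ev)
  expect_equal(as.vector(em$centroids), mu / sqrt(sum(mu^2)),
               tolerance = 1e-12)
})

test_that("global-state occupancy is recovered within a few points", {
  probs <- c(0.5, rep(0.5 / 7, 7))
  occ <- vapply(1:5, function(seed) {
    s <- simulate_bold(16, 2000, K_states = 8, noise_sd = 0.2, seed = seed,
                       state_probs = probs)
    ev <- leading_eigenvector_series(instantaneous_phase(s))
    em <- cluster_modes(ev, K = 8, seed = seed)
    # the recovered global mode is the centroid best matching all-ones
    sim <- abs(em$centroids %*% rep(1 / 4, 16))
    em$occupancy[which.max(sim)]
  }, numeric(1))
  expect_lt(abs(mean(occ) - 0.5), 0.05)
})

test_that("parcel projection matches a per-node brute force and honours
           symmetry", {
  mesh <- phantom_mesh
  n <- nrow(mesh$nodes)
  centroid <- colMeans(mesh$nodes)
  # uniform radial field: all z-scores zero
  rad <- sweep(mesh$nodes, 2, centroid)
  rad <- rad / sqrt(rowSums(rad^2))
  uniform <- as.vector(t(rad))
  expect_equal(project_mode_to_parcels(uniform, mesh), rep(0, 8))
  # generic field vs naive aggregation
  set.seed(11)
  fld <- rnorm(3 * n)
  got <- project_mode_to_parcels(fld, mesh)
  labeled <- which(!is.na(mesh$parcel))
  means <- vapply(sort(unique(mesh$parcel[labeled])), function(p) {
    sel <- labeled[mesh$parcel[labeled] == p]
    vals <- vapply(sel, function(i) {
      u <- fld[(3 * i - 2):(3 * i)]
      r <- mesh$nodes[i, ] - centroid
      sum(u * r / sqrt(sum(r^2)))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_equal(got, (means - mean(means)) / sd(means), tolerance = 1e-12)
})

test_that("eigenmode-to-empirical matching is sign-invariant with exact
           extremes", {
  set.seed(12)
  C <- matrix(rnorm(4 * 10), 4)
  C <- C / sqrt(rowSums(C^2))
  mt <- match_eigenmodes_to_empirical(-2 * C[2, ], C)
  expect_equal(max(mt$similarity), 1)
  expect_identical(mt$best_match$empirical[1], 2L)
  v <- c(1, rep(0, 9)); w <- c(0, 1, rep(0, 8))
  expect_equal(match_eigenmodes_to_empirical(rbind(v), rbind(w))$similarity[1, 1], 0)
  expect_error(match_eigenmodes_to_empirical(rbind(c(1, 2)), C), "mismatch")
})
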