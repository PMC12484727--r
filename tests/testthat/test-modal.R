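test_that("free-free body has exactly six rigid-body modes", {
  sys <- assemble(ball_mesh, ball_materials)
  res <- solve_modes(sys, n_modes = 10)
  expect_identical(sum(res$frequencies_hz < 1e-4), 6L)
  # the elastic modes are well separated from zero
  expect_gt(res$frequencies_hz[7], 1)
})

test_that("constrained system has no rigid-body modes", {
  sys <- apply_dirichlet(assemble(ball_mesh, ball_materials),
                         ball_mesh, "base")
  res <- solve_modes(sys, n_modes = 8)
  expect_identical(sum(res$frequencies_hz < 1e-4), 0L)
  expect_true(all(diff(res$frequencies_hz) >= 0))
  expect_equal(res$omegas, 2 * pi * res$frequencies_hz)
})

test_that("fixed-free bar recovers the closed-form axial frequency and
           converges under refinement", {
  f_exact <- (1 / (4 * 100)) * sqrt(1 / 1e-9)   # (1/4L) sqrt(E/rho)
  axial_freq <- function(n_div) {
    bar <- build_bar_mesh(100, 10, n_div)
    sys <- apply_dirichlet(assemble(bar, bar_materials), bar, "fixed_end")
    res <- solve_modes(sys, n_modes = 8)
    full <- expand_to_full(res, sys)
    xdofs <- seq(1, 3 * sys$n_nodes, 3)
    part <- colSums(full[xdofs, ]^2) / colSums(full^2)
    res$frequencies_hz[which.max(part)]
  }
  err <- abs(c(axial_freq(12), axial_freq(24)) - f_exact) / f_exact
  expect_lt(err[1], 0.03)
  expect_lt(err[2], err[1])
})

test_that("shift-invert frequencies match the dense full-spectrum oracle", {
  for (fixture in list(
    list(mesh = tiny_bar, mats = bar_materials, fix = "fixed_end"),
    list(mesh = tiny_ball_mesh, mats = ball_materials, fix = "base"))) {
    sys <- apply_dirichlet(assemble(fixture$mesh, fixture$mats),
                           fixture$mesh, fixture$fix)
    expect_lte(sys$n_free, 600)
    k <- 10
    si <- solve_modes(sys, n_modes = k)
    de <- solve_modes_dense(sys, n_modes = k)
    expect_lt(max(abs(si$frequencies_hz / de$frequencies_hz - 1)), 1e-8)
    expect_gt(min(diag(mac_matrix(si, de))), 1 - 1e-8)
  }
})

test_that("modes are M-orthogonal with consistent Rayleigh quotients", {
  sys <- apply_dirichlet(assemble(ball_mesh, ball_materials),
                         ball_mesh, "base")
  res <- solve_modes(sys, n_modes = 8)
  S <- res$shapes
  G <- crossprod(S, as.matrix(sys$M %*% S))
  offdiag <- abs(G - diag(diag(G))) / sqrt(outer(diag(G), diag(G)))
  expect_lt(max(offdiag), 1e-6)
  for (i in seq_len(ncol(S))) {
    rq <- sum(S[, i] * as.numeric(sys$K %*% S[, i])) /
      sum(S[, i] * as.numeric(sys$M %*% S[, i]))
    expect_equal(rq, res$omegas[i]^2, tolerance = 1e-8)
  }
  expect_true(all(res$residuals <= 1e-6))
})

test_that("doubling every modulus scales frequencies by sqrt(2) exactly and
           leaves shapes unchanged", {
  sys1 <- apply_dirichlet(assemble(ball_mesh, ball_materials),
                          ball_mesh, "base")
  sys2 <- apply_dirichlet(
    assemble(ball_mesh, scale_stiffness(ball_materials, 2)),
    ball_mesh, "base")
  r1 <- solve_modes(sys1, n_modes = 8)
  r2 <- solve_modes(sys2, n_modes = 8)
  expect_lt(max(abs(r2$frequencies_hz / r1$frequencies_hz - sqrt(2))), 1e-10)
  expect_gt(min(diag(mac_matrix(r1, r2))), 1 - 1e-10)
})

test_that("normalization pins the largest entry to +1 and is idempotent", {
  sys <- apply_dirichlet(assemble(tiny_bar, bar_materials),
                         tiny_bar, "fixed_end")
  res <- solve_modes(sys, n_modes = 5)
  for (i in 1:5) {
    expect_equal(max(res$shapes[, i]), 1)
    expect_lte(max(abs(res$shapes[, i])), 1)
  }
  res2 <- normalize_modes(res)
  expect_equal(res2$shapes, res$shapes)
  expect_equal(mac(res$shapes[, 1], normalize_modes(res)$shapes[, 1]), 1)
})

test_that("expansion to the full field zeroes fixed DOFs and round-trips", {
  sys <- apply_dirichlet(assemble(tiny_bar, bar_materials),
                         tiny_bar, "fixed_end")
  res <- solve_modes(sys, n_modes = 4)
  full <- expand_to_full(res, sys)
  expect_identical(nrow(full), 3L * sys$n_nodes)
  fixed_dofs <- setdiff(seq_len(3 * sys$n_nodes), sys$free_dofs)
  expect_true(all(full[fixed_dofs, ] == 0))
  expect_equal(full[sys$free_dofs, ], res$shapes, ignore_attr = TRUE)
  # mismatched dof maps are rejected
  other <- apply_dirichlet(assemble(tiny_bar, bar_materials),
                           tiny_bar, "free_end")
  expect_error(expand_to_full(res, other), "mismatch")
})

test_that("solver input validation", {
  sys <- apply_dirichlet(assemble(tiny_bar, bar_materials),
                         tiny_bar, "fixed_end")
  expect_error(solve_modes(sys, n_modes = sys$n_free), "n_modes")
})

test_that("repeated solves with one seed are deterministic", {
  sys <- apply_dirichlet(assemble(tiny_ball_mesh, ball_materials),
                         tiny_ball_mesh, "base")
  r1 <- solve_modes(sys, n_modes = 6, seed = 42)
  r2 <- solve_modes(sys, n_modes = 6, seed = 42)
  expect_identical(r1$frequencies_hz, r2$frequencies_hz)
  expect_identical(r1$shapes, r2$shapes)
})
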