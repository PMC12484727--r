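# quadrature oracle: integrate B^T D B over the tet at 5 barycentric
# points, with B rebuilt independently from a Vandermonde solve at each
# point (the integrand is constant, so agreement must be exact)
quadrature_stiffness <- function(coords, E, nu) {
  A <- cbind(1, coords)
  Cmat <- solve(A)
  shape_grad <- function(p) t(Cmat[2:4, ])       # linear: same everywhere
  D <- elasticity_matrix(E, nu)
  V <- abs(det(A)) / 6
  bary <- rbind(c(0.25, 0.25, 0.25, 0.25),
                c(0.5, 1 / 6, 1 / 6, 1 / 6),
                c(1 / 6, 0.5, 1 / 6, 1 / 6),
                c(1 / 6, 1 / 6, 0.5, 1 / 6),
                c(1 / 6, 1 / 6, 1 / 6, 0.5))
  w <- c(-0.8, 0.45, 0.45, 0.45, 0.45)           # 5-point tet rule weights
  Ke <- matrix(0, 12, 12)
  for (q in 1:5) {
    p <- bary[q, ] %*% coords
    G <- shape_grad(p)
    B <- matrix(0, 6, 12)
    for (i in 1:4) {
      col <- 3 * (i - 1)
      B[1, col + 1] <- G[i, 1]
      B[2, col + 2] <- G[i, 2]
      B[3, col + 3] <- G[i, 3]
      B[4, col + 1] <- G[i, 2]; B[4, col + 2] <- G[i, 1]
      B[5, col + 2] <- G[i, 3]; B[5, col + 3] <- G[i, 2]
      B[6, col + 1] <- G[i, 3]; B[6, col + 3] <- G[i, 1]
    }
    Ke <- Ke + w[q] * V * t(B) %*% D %*% B
  }
  Ke
}

unit_tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

test_that("element stiffness matches the quadrature oracle and has the
           rigid-body null space", {
  for (case in list(list(E = 1, nu = 0), list(E = 2.5, nu = 0.3))) {
    Ke <- element_stiffness(unit_tet, case$E, case$nu)
    expect_equal(Ke, quadrature_stiffness(unit_tet, case$E, case$nu),
                 tolerance = 1e-12)
    expect_equal(Ke, t(Ke))
    # translations
    for (d in 1:3) {
      u <- rep(0, 12); u[seq(d, 12, 3)] <- 1
      expect_lt(max(abs(Ke %*% u)), 1e-12)
    }
    # infinitesimal rotations about the centroid
    cen <- colMeans(unit_tet)
    for (axis in 1:3) {
      omega <- rep(0, 3); omega[axis] <- 1
      u <- as.vector(apply(unit_tet, 1, function(x)
        cross3(omega, x - cen)))   # columns per node -> x1,y1,z1,x2,...
      expect_lt(max(abs(Ke %*% u)), 1e-12)
    }
    # exactly 6 (near-)zero eigenvalues
    ev <- eigen(Ke, symmetric = TRUE, only.values = TRUE)$values
    expect_identical(sum(abs(ev) < 1e-10 * max(ev)), 6L)
  }
})

test_that("degenerate elements are rejected", {
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(element_stiffness(flat, 1, 0.3), "degenerate")
  expect_error(element_mass(flat, 1), "degenerate")
})

test_that("consistent element mass conserves mass and is positive definite", {
  Me <- element_mass(unit_tet, rho = 1)
  V <- 1 / 6
  # closed form: diagonal 2 * (rho V / 20) = 1/60 on the unit tet
  expect_equal(Me[1, 1], 1 / 60)
  # per-direction entries sum to rho V
  for (d in 1:3) {
    idx <- seq(d, 12, 3)
    expect_equal(sum(Me[idx, idx]), V)
  }
  expect_gt(min(eigen(Me, symmetric = TRUE, only.values = TRUE)$values), 0)
  # lumped variant: diagonal, same total mass
  Ml <- element_mass(unit_tet, rho = 1, lumped = TRUE)
  expect_true(all(Ml[row(Ml) != col(Ml)] == 0))
  expect_equal(sum(diag(Ml)), 3 * V)
})

test_that("assembly equals hand scattering of element matrices", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  tets <- fix_orientation(rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)), nodes)
  mesh <- labeled_mesh(nodes, tets, c("WM", "GM"))
  mats <- material_set(WM = list(E = 2, rho = 1e-9, nu = 0.3),
                       GM = list(E = 5, rho = 2e-9, nu = 0.4))
  sys <- assemble(mesh, mats)
  Kh <- Mh <- matrix(0, 15, 15)
  for (e in 1:2) {
    dofs <- as.vector(rbind(3 * tets[e, ] - 2, 3 * tets[e, ] - 1,
                            3 * tets[e, ]))
    m <- mats[[mesh$region[e]]]
    Kh[dofs, dofs] <- Kh[dofs, dofs] +
      element_stiffness(nodes[tets[e, ], ], m$E, m$nu)
    Mh[dofs, dofs] <- Mh[dofs, dofs] + element_mass(nodes[tets[e, ], ], m$rho)
  }
  expect_equal(as.matrix(sys$K), Kh, ignore_attr = TRUE, tolerance = 1e-14)
  expect_equal(as.matrix(sys$M), Mh, ignore_attr = TRUE, tolerance = 1e-14)
})

test_that("global matrices conserve mass and annihilate translations", {
  sys <- assemble(tiny_ball_mesh, ball_materials)
  n <- sys$n_nodes
  total_mass <- ball_materials$HOMOG$rho * mesh_volume(tiny_ball_mesh)
  for (d in 1:3) {
    ones <- rep(0, 3 * n); ones[seq(d, 3 * n, 3)] <- 1
    expect_equal(sum(ones * as.numeric(sys$M %*% ones)), total_mass)
    expect_lt(max(abs(sys$K %*% ones)), 1e-10 * max(abs(sys$K)))
  }
  expect_lt(max(abs(sys$K - Matrix::t(sys$K))), 1e-12)
  expect_lt(max(abs(sys$M - Matrix::t(sys$M))), 1e-20)
})

test_that("missing materials fail naming the region", {
  expect_error(assemble(phantom_mesh,
                        material_set(WM = list(E = 1, rho = 1e-9, nu = 0.3))),
               "GM")
})

test_that("Dirichlet elimination bookkeeping is exact", {
  sys <- assemble(tiny_bar, bar_materials)
  n <- sys$n_nodes
  red <- apply_dirichlet(sys, tiny_bar, tiny_bar$node_sets$fixed_end[1])
  expect_identical(red$n_free, 3L * (n - 1L))
  expect_error(apply_dirichlet(sys, tiny_bar, integer(0)), "empty")
  expect_error(apply_dirichlet(sys, tiny_bar, seq_len(n)), "fully constrained")
  expect_error(apply_dirichlet(sys, tiny_bar, "no_such_set"), "not found")
  # per-direction fixing
  red_x <- apply_dirichlet(sys, tiny_bar, "fixed_end", directions = 1)
  expect_identical(red_x$n_free,
                   3L * n - length(tiny_bar$node_sets$fixed_end))
})

test_that("base-fixed stiffness is positive definite on the free DOFs", {
  sys <- assemble(tiny_bar, bar_materials)
  red <- apply_dirichlet(sys, tiny_bar, "fixed_end")
  expect_lte(red$n_free, 300)
  ev <- eigen(as.matrix(red$K), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # M positive definite too
  evm <- eigen(as.matrix(red$M), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(evm), 0)
})

test_that("stiffness scales exactly with a global modulus factor and is
           monotone in any single region's modulus", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  tets <- fix_orientation(rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)), nodes)
  mesh <- labeled_mesh(nodes, tets, c("WM", "CSF"))
  mats <- material_set(WM = list(E = 2, rho = 1e-9, nu = 0.3),
                       CSF = list(E = 0.5, rho = 1e-9, nu = 0.4))
  K1 <- assemble(mesh, mats)$K
  K3 <- assemble(mesh, scale_stiffness(mats, 3))$K
  expect_equal(as.matrix(K3), 3 * as.matrix(K1), tolerance = 1e-14)
  # raising one region's E adds a positive semi-definite increment
  K_up <- assemble(mesh, set_region_stiffness(mats, "CSF", 1.7))$K
  dK <- as.matrix(K_up - K1)
  ev <- eigen((dK + t(dK)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-12 * max(abs(ev)))
})
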