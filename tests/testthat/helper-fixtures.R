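# Shared fixtures, built once per test run. Sizes are chosen so the whole
# suite runs in minutes on one CPU while every mesh still has several
# elements through each shell thickness.

# single-region ball, ~1.5k free DOFs: rigid-body and oracle tests
ball_config <- phantom_config(shell_radii = 50, target_edge_length = 18,
                              axes = c(1, 1, 1), n_parcels = 2, seed = 1)
ball_mesh <- build_layered_phantom(ball_config)
ball_materials <- material_set(
  HOMOG = list(E = 0.0232, rho = 1.04e-9, nu = 0.45))

# tiny ball, < 600 DOFs: dense-oracle comparisons
tiny_ball_mesh <- build_layered_phantom(
  phantom_config(shell_radii = 50, target_edge_length = 30,
                 axes = c(1, 1, 1), n_parcels = 2, seed = 1))

# four-shell head phantom at coarse desk scale
phantom_cfg <- phantom_config(shell_radii = c(45, 55, 60, 65),
                              target_edge_length = 16, n_parcels = 8,
                              appendage_radius = 22, seed = 1)
phantom_mesh <- build_layered_phantom(phantom_cfg)

# tiny structured bar, < 300 free DOFs
tiny_bar <- build_bar_mesh(100, 30, 6)
bar_materials <- material_set(HOMOG = list(E = 1, rho = 1e-9, nu = 0))

expect_mesh_valid <- function(mesh) {
  expect_silent(validate_mesh(mesh))
  expect_gt(min(tet_volumes(mesh)), 0)
}
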