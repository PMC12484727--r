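# Drivers run on a deliberately coarse phantom so the whole file stays
# fast; scientific assertions are about structure, trends and exact laws,
# which hold at any resolution.
exp_spec <- experiment_spec(
  phantom = phantom_config(shell_radii = c(45, 55, 60, 65),
                           target_edge_length = 18, n_parcels = 8,
                           appendage_radius = 22, seed = 1),
  n_modes = 8, seed = 1)

test_that("complexity comparison books every mode as paired or unique", {
  rep <- run_complexity_comparison(exp_spec)
  expect_identical(rep$n_paired + rep$n_unique_het, exp_spec$n_modes)
  expect_identical(rep$n_paired + rep$n_unique_hom, exp_spec$n_modes)
  expect_setequal(unique(rep$mesh$region), c("WM", "GM", "CSF"))
  # identical materials on the same mesh: all modes pair exactly
  same <- run_complexity_comparison(
    exp_spec,
    materials_het = material_presets("complexity_homogeneous"),
    materials_hom = material_presets("complexity_homogeneous"))
  expect_identical(same$n_paired, exp_spec$n_modes)
  expect_equal(same$comparison$pairs$mac, rep(1, exp_spec$n_modes),
               tolerance = 1e-9)
  expect_equal(same$comparison$pairs$nrfd, rep(0, exp_spec$n_modes),
               tolerance = 1e-9)
})

test_that("stiffer-CSF heterogeneous model never undercuts the homogeneous
           frequencies when its stiffness dominates", {
  # homogeneous E below every heterogeneous region's E: K_het - K_hom psd,
  # so by Courant-Fischer no eigenfrequency decreases
  hom <- material_set(WM = list(E = 0.01537, rho = 1.05e-9, nu = 0.45),
                      GM = list(E = 0.01537, rho = 1.05e-9, nu = 0.45),
                      CSF = list(E = 0.01537, rho = 1.05e-9, nu = 0.45))
  rep <- run_complexity_comparison(exp_spec,
                                   materials_het = material_presets("complexity_heterogeneous"),
                                   materials_hom = hom)
  expect_true(all(rep$frequencies$f_heterogeneous >=
                  rep$frequencies$f_homogeneous - 1e-9))
})

test_that("boundary-condition comparison reproduces the distance trend and
           reports every scenario", {
  rep <- run_bc_comparison(exp_spec)
  expect_named(rep$modal, c("skull", "neck", "spine", "fmri", "noskull"))
  for (m in rep$modal) expect_identical(m$n_converged >= exp_spec$n_modes, TRUE)
  # frequencies drop as the fixed boundary moves away from the brain
  expect_lt(rep$fundamental[["spine"]], rep$fundamental[["neck"]])
  expect_lt(rep$fundamental[["neck"]], rep$fundamental[["skull"]])
  expect_true(rep$trend_ok)
  # the no-skull vs fMRI comparison reports per-pair NRFD
  nk <- rep$comparisons$noskull_vs_fmri
  expect_s3_class(nk, "mode_comparison")
  expect_true(all(c("mac", "nrfd") %in% names(nk$pairs)))
  expect_gte(rep$n_distinct_shapes, exp_spec$n_modes)
})

test_that("CSF sweep is monotone with non-decreasing fundamental NRFD", {
  rep <- run_csf_sweep(exp_spec, grid = c(2.19, 0.299, 0.012))
  expect_true(rep$monotone_frequencies)
  expect_true(rep$nrfd_fundamental_nondecreasing)
  expect_equal(unname(rep$nrfd_fundamental[1]), 0)
  # reference point compares to itself exactly
  expect_equal(diag(mac_matrix(rep$modal[[1]], rep$modal[[1]])),
               rep(1, exp_spec$n_modes))
  # per-point comparisons exist for the non-reference grid points
  expect_named(rep$comparisons, c("0.299", "0.012"))
})

test_that("ratio hypothesis: global scaling is exact; c = 1 is the identity", {
  rep <- run_ratio_hypothesis(exp_spec, scale_factor = 4)
  expect_lt(abs(rep$exact_law$freq_ratio_err), 1e-8)
  expect_gt(rep$exact_law$mac_min, 1 - 1e-6)
  # scale 4 doubles every frequency
  cmp <- rep$exact_law$comparison
  expect_equal(cmp$pairs$f_val / cmp$pairs$f_ref,
               rep(2, nrow(cmp$pairs)), tolerance = 1e-8)
  expect_true(all(c("n_above_0.8", "n_0.5_to_0.8") %in% names(rep$mixed)))
})

test_that("run_all writes a reproducible manifest", {
  spec <- experiment_spec(
    phantom = phantom_config(shell_radii = c(45, 55, 60, 65),
                             target_edge_length = 20, n_parcels = 4,
                             appendage_radius = 22, seed = 1),
    n_modes = 6, seed = 1, out_dir = withr::local_tempdir())
  all1 <- run_all_experiments(spec)
  all2 <- run_all_experiments(spec)
  drop_ts <- function(m) m[setdiff(names(m), "timestamp")]
  expect_identical(drop_ts(all1$manifest), drop_ts(all2$manifest))
  expect_named(all1$reports, c("complexity", "bc", "csf_sweep", "ratio"))
  expect_true(file.exists(file.path(spec$out_dir, "manifest.json")))
  expect_true(file.exists(file.path(spec$out_dir,
                                    "complexity_frequencies.csv")))
  # the hash tracks the scientific configuration
  spec_mat <- experiment_spec(phantom = spec$phantom, n_modes = 6, seed = 1,
                              materials = list(bc = material_presets("bc_reference")))
  expect_false(identical(all1$manifest$config_hash, brainmodes:::spec_hash(spec_mat)))
  mats2 <- list(bc = set_region_stiffness(material_presets("bc_reference"),
                                          "CSF", 99))
  spec_mat2 <- experiment_spec(phantom = spec$phantom, n_modes = 6, seed = 1,
                               materials = mats2)
  expect_false(identical(brainmodes:::spec_hash(spec_mat), brainmodes:::spec_hash(spec_mat2)))
})
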