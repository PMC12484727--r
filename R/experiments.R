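# Experiment drivers reproducing the study design at phantom scale:
# model-complexity comparison, five-boundary-condition comparison,
# CSF-stiffness sweeps under two brain-stiffness scenarios, and the
# stiffness-ratio hypothesis. Phantom meshes are ~10^3-10^4 elements, so
# absolute frequencies are mesh-specific; the experiments assert trends,
# exact laws and in-study arithmetic, never literature Hz values.

#' Experiment specification
#'
#' @param phantom a [phantom_config()] for the shared phantom family.
#' @param n_modes modes to extract per scenario (default 25).
#' @param threshold MAC pairing threshold (default 0.5).
#' @param seed seed for the eigensolver start vectors.
#' @param materials optional named list of [material_set()] overrides for
#'   the drivers (`heterogeneous`, `homogeneous`, `bc`, `csf_high`,
#'   `csf_low`); included in the manifest's config hash, so changing any
#'   material value changes the hash.
#' @param out_dir optional output directory; when set, the drivers write
#'   CSV tables, JSON summaries and PNG heatmaps there.
#' @return an object of class `experiment_spec`.
#' @export
experiment_spec <- function(phantom = phantom_config(), n_modes = 25,
                            threshold = 0.5, seed = 1L, materials = NULL,
                            out_dir = NULL) {
  stopifnot(inherits(phantom, "phantom_config"), n_modes >= 1)
  structure(list(phantom = phantom, n_modes = as.integer(n_modes),
                 threshold = threshold, seed = as.integer(seed),
                 materials = materials, out_dir = out_dir),
            class = "experiment_spec")
}

# material override helper: spec-supplied set, else preset
spec_materials <- function(spec, key, default) {
  if (!is.null(spec$materials[[key]])) spec$materials[[key]] else default
}

# assemble + constrain + solve in one step
solve_scenario <- function(mesh, materials, fix_set, n_modes, seed,
                           directions = 1:3) {
  sys <- assemble(mesh, materials)
  sys <- apply_dirichlet(sys, mesh, fix_set, directions)
  solve_modes(sys, n_modes = n_modes, seed = seed)
}

#' Model-complexity comparison (heterogeneous vs homogeneous brain)
#'
#' Both models share one skull-stripped phantom mesh with the entire
#' exterior surface fixed, so quantitative MAC comparison is defined. The
#' heterogeneous model assigns WM/GM/CSF their own moduli; the homogeneous
#' model one brain-average modulus.
#'
#' @param spec an [experiment_spec()].
#' @param materials_het,materials_hom material sets (defaults: the
#'   model-complexity presets of [material_presets()]).
#' @return list with the shared `mesh`, both frequency tables, the
#'   `mode_comparison` (heterogeneous as NRFD reference), and the
#'   paired/unique bookkeeping.
#' @export
run_complexity_comparison <- function(spec,
    materials_het = spec_materials(spec, "heterogeneous",
                                   material_presets("complexity_heterogeneous")),
    materials_hom = spec_materials(spec, "homogeneous",
                                   material_presets("complexity_homogeneous"))) {
  stopifnot(inherits(spec, "experiment_spec"))
  mesh <- strip_skull(build_layered_phantom(spec$phantom))
  het <- solve_scenario(mesh, materials_het, "exterior", spec$n_modes,
                        spec$seed)
  hom <- solve_scenario(mesh, materials_hom, "exterior", spec$n_modes,
                        spec$seed)
  cmp <- compare_modes(het, hom, spec$threshold)
  out <- list(mesh = mesh,
              frequencies = data.frame(
                mode = seq_len(spec$n_modes),
                f_heterogeneous = het$frequencies_hz,
                f_homogeneous = hom$frequencies_hz),
              comparison = cmp,
              n_paired = nrow(cmp$pairs),
              n_unique_het = length(cmp$unpaired_a),
              n_unique_hom = length(cmp$unpaired_b),
              modal_het = het, modal_hom = hom)
  maybe_write_report(spec, "complexity", out)
  out
}

#' Boundary-condition comparison across the five fixation scenarios
#'
#' Runs the shared phantom family under: skull-base fixation, neck
#' cylinder (base fixed), spine cylinder (base fixed), fMRI-style
#' base+back+sides fixation, and no-skull with the entire brain exterior
#' fixed. Scenarios are compared pairwise on their shared brain nodes;
#' distinct mode shapes across scenarios are counted with a greedy
#' MAC-threshold library.
#'
#' @param spec an [experiment_spec()].
#' @param materials material set (default: the head-and-neck reference
#'   preset, skull material on neck/spine).
#' @return list with per-scenario frequency table, pairwise
#'   `mode_comparison`s, the distinct-shape count and the
#'   boundary-distance frequency trend check.
#' @export
run_bc_comparison <- function(spec,
    materials = spec_materials(spec, "bc", material_presets("bc_reference"))) {
  stopifnot(inherits(spec, "experiment_spec"))
  base_cfg <- spec$phantom
  phantom <- build_layered_phantom(base_cfg)
  meshes <- list(
    skull = phantom,
    neck = attach_cylinder(phantom, 120, base_cfg$appendage_radius, "NECK"),
    spine = attach_cylinder(phantom, 500, base_cfg$appendage_radius, "SPINE"),
    fmri = phantom,
    noskull = strip_skull(phantom))
  fix_sets <- c(skull = "base", neck = "cylinder_base",
                spine = "cylinder_base", fmri = "base_back_sides",
                noskull = "exterior")
  modal <- list()
  for (nm in names(meshes))
    modal[[nm]] <- solve_scenario(meshes[[nm]], materials, fix_sets[[nm]],
                                  spec$n_modes, spec$seed)

  freqs <- data.frame(mode = seq_len(spec$n_modes))
  for (nm in names(modal)) freqs[[nm]] <- modal[[nm]]$frequencies_hz

  pairs_to_compare <- list(c("skull", "neck"), c("skull", "spine"),
                           c("neck", "spine"), c("noskull", "fmri"),
                           c("skull", "fmri"))
  comparisons <- list()
  for (p in pairs_to_compare) {
    key <- paste(p, collapse = "_vs_")
    comparisons[[key]] <- compare_on_common_nodes(
      modal[[p[1]]], meshes[[p[1]]], modal[[p[2]]], meshes[[p[2]]],
      spec$threshold)
  }

  n_distinct <- count_distinct_shapes(modal, meshes, spec$threshold)
  f1 <- vapply(modal, function(m) m$frequencies_hz[1], numeric(1))
  trend_ok <- f1[["spine"]] < f1[["neck"]] && f1[["neck"]] < f1[["skull"]]

  out <- list(frequencies = freqs, comparisons = comparisons,
              fundamental = f1, trend_ok = trend_ok,
              n_distinct_shapes = n_distinct, modal = modal,
              meshes = meshes)
  maybe_write_report(spec, "bc", out)
  out
}

# Greedy distinct-shape count over scenarios: a mode is new if its best
# MAC against the library (on the shared brain-node DOFs) is below the
# threshold.
count_distinct_shapes <- function(modal, meshes, threshold) {
  origin <- lapply(meshes, function(m) {
    o <- attr(m, "node_origin")
    if (is.null(o)) seq_len(nrow(m$nodes)) else o
  })
  common <- Reduce(intersect, origin)
  lib <- NULL
  n_distinct <- 0L
  for (nm in names(modal)) {
    idx <- match(common, origin[[nm]])
    dofs <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
    S <- expand_to_full(modal[[nm]])[dofs, , drop = FALSE]
    S <- S[, colSums(S^2) > 0, drop = FALSE]
    for (i in seq_len(ncol(S))) {
      if (is.null(lib) || max(crossprod(lib, S[, i])^2 /
                              (colSums(lib^2) * sum(S[, i]^2))) < threshold) {
        lib <- cbind(lib, S[, i])
        n_distinct <- n_distinct + 1L
      }
    }
  }
  n_distinct
}

#' CSF Young's modulus sweep
#'
#' Varies the CSF stiffness over the literature grid (2.19 down to 0.001
#' MPa) with all other properties fixed, under skull-base fixation, and
#' compares every grid point with the stiffest (2.19 MPa) reference model.
#'
#' @param spec an [experiment_spec()].
#' @param brain `"high"` (GM 0.01537 / WM 0.03103 MPa) or `"low"`
#'   (GM 0.001389 / WM 0.001895 MPa) brain-stiffness scenario.
#' @param grid CSF moduli in MPa, decreasing; first entry is the
#'   reference (default [csf_stiffness_grid()]).
#' @return list with the frequency table (mode x grid point), per-point
#'   `mode_comparison`s vs the reference, the frequency-monotonicity and
#'   fundamental-NRFD checks, and the MAC-vs-frequency rank correlation.
#' @export
run_csf_sweep <- function(spec, brain = c("high", "low"),
                          grid = csf_stiffness_grid()) {
  stopifnot(inherits(spec, "experiment_spec"))
  brain <- match.arg(brain)
  base_mat <- spec_materials(spec, paste0("csf_", brain),
                             material_presets(paste0("csf_sweep_", brain)))
  mesh <- build_layered_phantom(spec$phantom)

  modal <- list()
  for (E in grid) {
    mats <- set_region_stiffness(base_mat, "CSF", E)
    modal[[as.character(E)]] <- solve_scenario(mesh, mats, "base",
                                               spec$n_modes, spec$seed)
  }
  freqs <- sapply(modal, function(m) m$frequencies_hz)
  colnames(freqs) <- paste0("E_csf_", grid)

  ref <- modal[[1]]
  comparisons <- list()
  for (j in seq_along(grid)[-1])
    comparisons[[as.character(grid[j])]] <-
      compare_modes(ref, modal[[j]], spec$threshold)

  # decreasing CSF E must not increase any sorted eigenfrequency
  mono_ok <- all(diff(t(freqs)) <= 1e-8 * t(freqs)[-nrow(t(freqs)), ])
  nrfd_fund <- nrfd(ref$frequencies_hz[1],
                    freqs[1, ])
  nrfd_ok <- all(diff(nrfd_fund) >= -1e-12)

  # qualitative trend: MAC decreasing with mode frequency (rank corr.)
  mac_trend <- vapply(comparisons, function(cmp) {
    if (nrow(cmp$pairs) < 3) return(NA_real_)
    stats::cor(cmp$pairs$f_ref, cmp$pairs$mac, method = "spearman")
  }, numeric(1))

  out <- list(grid = grid, brain = brain, frequencies = freqs,
              comparisons = comparisons, monotone_frequencies = mono_ok,
              nrfd_fundamental = nrfd_fund,
              nrfd_fundamental_nondecreasing = nrfd_ok,
              mac_frequency_rank_correlation = mac_trend,
              modal = modal, mesh = mesh)
  maybe_write_report(spec, paste0("csf_sweep_", brain), out)
  out
}

#' Stiffness-ratio hypothesis
#'
#' Probes whether mode shapes follow the brain-to-CSF stiffness ratio
#' rather than absolute stiffness. Two parts:
#' \describe{
#'   \item{exact law}{scaling every region's E by one constant `c` leaves
#'     shapes unchanged (MAC = 1) and multiplies every frequency by
#'     `sqrt(c)` — checked to near machine precision.}
#'   \item{approximate ratio pairs}{the study's mixed pairs (higher brain
#'     stiffness with CSF 1 kPa vs lower brain stiffness with CSF 0.1
#'     kPa, and the 12 kPa vs 1 kPa pairing): MAC distributions are
#'     reported, not asserted.}
#' }
#'
#' @param spec an [experiment_spec()].
#' @param scale_factor the global stiffness scale `c` for the exact-law
#'   part (default 0.1, i.e. one decade softer).
#' @return list with `exact_law` (min pair MAC, max |f-ratio - sqrt(c)|),
#'   `mixed` and `twelve_vs_one` comparison summaries.
#' @export
run_ratio_hypothesis <- function(spec, scale_factor = 0.1) {
  stopifnot(inherits(spec, "experiment_spec"))
  mesh <- build_layered_phantom(spec$phantom)
  high <- material_presets("csf_sweep_high")
  low <- material_presets("csf_sweep_low")

  # exact global-scaling law
  m1 <- set_region_stiffness(high, "CSF", 0.001)
  m2 <- scale_stiffness(m1, scale_factor)
  r1 <- solve_scenario(mesh, m1, "base", spec$n_modes, spec$seed)
  r2 <- solve_scenario(mesh, m2, "base", spec$n_modes, spec$seed)
  cmp_exact <- compare_modes(r1, r2, spec$threshold)
  exact_law <- list(
    comparison = cmp_exact,
    mac_min = min(diag(mac_matrix(r1, r2))),
    freq_ratio_err = max(abs(r2$frequencies_hz / r1$frequencies_hz -
                             sqrt(scale_factor))))

  # approximate-ratio pair: high brain + CSF 1 kPa vs low brain + 0.1 kPa
  r3 <- solve_scenario(mesh, set_region_stiffness(low, "CSF", 1e-4),
                       "base", spec$n_modes, spec$seed)
  cmp_mixed <- compare_modes(r1, r3, spec$threshold)
  mixed <- summarize_mac(cmp_mixed)

  # the 12 kPa vs 1 kPa CSF pairing across brain stiffnesses
  r4 <- solve_scenario(mesh, set_region_stiffness(high, "CSF", 0.012),
                       "base", spec$n_modes, spec$seed)
  r5 <- solve_scenario(mesh, set_region_stiffness(low, "CSF", 0.001),
                       "base", spec$n_modes, spec$seed)
  cmp_12v1 <- compare_modes(r4, r5, spec$threshold)
  twelve_vs_one <- summarize_mac(cmp_12v1)

  out <- list(exact_law = exact_law, mixed = mixed,
              twelve_vs_one = twelve_vs_one, mesh = mesh)
  maybe_write_report(spec, "ratio", out)
  out
}

summarize_mac <- function(cmp) {
  full_mac <- cmp$mac[cbind(seq_len(min(dim(cmp$mac))),
                            seq_len(min(dim(cmp$mac))))]
  list(comparison = cmp,
       n_pairs = nrow(cmp$pairs),
       n_above_0.8 = sum(cmp$pairs$mac > 0.8),
       n_0.5_to_0.8 = sum(cmp$pairs$mac >= 0.5 & cmp$pairs$mac <= 0.8),
       mac_sorted_diag = full_mac)
}

#' Run all experiments and write a reproducibility manifest
#'
#' @param spec an [experiment_spec()].
#' @return list with `manifest` (config hash, seed, package version,
#'   per-experiment summaries, timestamp) and the four experiment reports.
#' @export
run_all_experiments <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  reports <- list(
    complexity = run_complexity_comparison(spec),
    bc = run_bc_comparison(spec),
    csf_sweep = run_csf_sweep(spec),
    ratio = run_ratio_hypothesis(spec))
  manifest <- list(
    config_hash = spec_hash(spec),
    seed = spec$seed,
    n_modes = spec$n_modes,
    threshold = spec$threshold,
    package_version = as.character(utils::packageVersion("brainmodes")),
    experiments = lapply(reports, summarize_report),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(spec$out_dir)) {
    dir.create(spec$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(spec$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(manifest = manifest, reports = reports)
}

summarize_report <- function(rep) {
  if (!is.null(rep$n_paired))
    return(list(kind = "complexity", n_paired = rep$n_paired,
                n_unique_het = rep$n_unique_het,
                n_unique_hom = rep$n_unique_hom))
  if (!is.null(rep$n_distinct_shapes))
    return(list(kind = "bc", n_distinct_shapes = rep$n_distinct_shapes,
                trend_ok = rep$trend_ok,
                fundamental = as.list(rep$fundamental)))
  if (!is.null(rep$monotone_frequencies))
    return(list(kind = "csf_sweep", brain = rep$brain,
                monotone_frequencies = rep$monotone_frequencies,
                nrfd_fundamental = unname(rep$nrfd_fundamental)))
  if (!is.null(rep$exact_law))
    return(list(kind = "ratio",
                exact_mac_min = rep$exact_law$mac_min,
                exact_freq_ratio_err = rep$exact_law$freq_ratio_err,
                mixed_n_above_0.8 = rep$mixed$n_above_0.8))
  list(kind = "unknown")
}

# deterministic hash of an experiment_spec's scientific content
# (out_dir excluded)
spec_hash <- function(spec) {
  core <- spec[setdiff(names(spec), "out_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(core, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

# Optional report writing: CSV frequency tables, JSON summary and (when
# ggplot2 renders without error) MAC/NRFD heatmap PNGs.
maybe_write_report <- function(spec, name, report) {
  if (is.null(spec$out_dir)) return(invisible(NULL))
  dir.create(spec$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$frequencies))
    utils::write.csv(as.data.frame(report$frequencies),
                     file.path(spec$out_dir, paste0(name, "_frequencies.csv")),
                     row.names = FALSE)
  cmps <- if (!is.null(report$comparisons)) report$comparisons
          else if (!is.null(report$comparison)) list(main = report$comparison)
  for (nm in names(cmps)) {
    cmp <- cmps[[nm]]
    if (!inherits(cmp, "mode_comparison")) next
    utils::write.csv(cmp$pairs,
                     file.path(spec$out_dir,
                               paste0(name, "_", nm, "_pairs.csv")),
                     row.names = FALSE)
    try({
      ggplot2::ggsave(
        file.path(spec$out_dir, paste0(name, "_", nm, "_mac.png")),
        plot_mac_heatmap(cmp), width = 6, height = 5, dpi = 120)
      if (!is.null(cmp$pairs$nrfd))
        ggplot2::ggsave(
          file.path(spec$out_dir, paste0(name, "_", nm, "_nrfd.png")),
          plot_nrfd(cmp), width = 6, height = 4, dpi = 120)
    }, silent = TRUE)
  }
  invisible(NULL)
}
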