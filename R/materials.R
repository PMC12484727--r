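# Material property sets for heterogeneous isotropic linear elasticity.
#
# Unit system: mm / ton / s, hence stiffness in MPa (N/mm^2), density in
# ton/mm^3 and forces in N. With these units omega^2 from the eigenproblem
# is in s^-2 and f = omega/(2*pi) is in Hz with no conversion factor.

#' Per-region isotropic elastic constants
#'
#' @param ... one named argument per region label, each a list (or named
#'   vector) with components `E` (Young's modulus, MPa), `rho` (density,
#'   ton/mm^3) and `nu` (Poisson's ratio).
#' @param nu_cap upper cap applied to all Poisson's ratios. Linear (C3D4)
#'   displacement tetrahedra lock volumetrically as nu -> 0.5, which biases
#'   eigenfrequencies upward; nearly incompressible literature values such
#'   as nu = 0.4999 are therefore capped at 0.49 by default. Set
#'   `nu_cap = NULL` to use the literature values verbatim.
#'
#' @return an object of class `material_set`: a named list of
#'   `list(E, rho, nu)` per region.
#' @examples
#' material_set(
#'   WM  = list(E = 0.03103, rho = 1.05e-9, nu = 0.45),
#'   GM  = list(E = 0.01537, rho = 1.05e-9, nu = 0.45),
#'   CSF = list(E = 0.299,   rho = 1.00e-9, nu = 0.4999),
#'   SKULL = list(E = 6000,  rho = 3.50e-9, nu = 0.22))
#' @export
material_set <- function(..., nu_cap = 0.49) {
  regions <- list(...)
  if (length(regions) == 1 && is.null(names(regions)) &&
      is.list(regions[[1]]) && !is.null(names(regions[[1]])) &&
      !all(c("E", "rho", "nu") %in% names(regions[[1]])))
    regions <- regions[[1]]
  if (is.null(names(regions)) || any(names(regions) == ""))
    stop("every region must be named")
  out <- lapply(regions, function(m) {
    m <- as.list(m)
    if (!all(c("E", "rho", "nu") %in% names(m)))
      stop("each region needs E, rho and nu")
    m <- lapply(m[c("E", "rho", "nu")], as.numeric)
    if (m$E <= 0) stop("E must be > 0")
    if (m$rho <= 0) stop("rho must be > 0")
    if (m$nu < 0 || m$nu >= 0.5) stop("nu must satisfy 0 <= nu < 0.5")
    if (!is.null(nu_cap)) m$nu <- min(m$nu, nu_cap)
    m
  })
  structure(out, class = "material_set", nu_cap = nu_cap)
}

#' Scale all Young's moduli of a material set
#'
#' With nu and rho fixed, `E -> c E` for every region scales the global
#' stiffness matrix exactly by `c`, so all eigenfrequencies scale by
#' `sqrt(c)` and mode shapes are unchanged — the sharp form of the
#' stiffness-ratio finding probed by [run_ratio_hypothesis()].
#'
#' @param materials a [material_set()].
#' @param factor positive scale factor applied to every region's `E`.
#' @return the scaled `material_set`.
#' @export
scale_stiffness <- function(materials, factor) {
  stopifnot(inherits(materials, "material_set"), factor > 0)
  out <- lapply(materials, function(m) { m$E <- m$E * factor; m })
  structure(out, class = "material_set", nu_cap = attr(materials, "nu_cap"))
}

#' Literature material parameter presets
#'
#' Named parameter combinations used by the analysis drivers, drawn from
#' published brain finite-element studies:
#' \describe{
#'   \item{complexity_heterogeneous}{WM 0.03103 / GM 0.01537 / CSF 0.299
#'     MPa, densities 1.05e-9 (brain) and 1.00e-9 (CSF) ton/mm^3, nu 0.45
#'     (the model-complexity comparison).}
#'   \item{complexity_homogeneous}{single brain material, E = 0.02320 MPa,
#'     rho = 1.04e-9 ton/mm^3, nu = 0.4999 (capped by `nu_cap`).}
#'   \item{bc_reference}{the head-and-neck reference parameter set used in
#'     the boundary-condition comparison: brain E 0.497 MPa (WM = GM), CSF
#'     1.314 MPa, skull 8000 MPa; densities 1.14e-9 / 1.04e-9 / 4.79e-9;
#'     nu 0.48 / 0.4999 / 0.22. Neck and spine cylinders take the skull
#'     material.}
#'   \item{csf_sweep_high / csf_sweep_low}{the CSF-stiffness sweep bases:
#'     higher brain stiffness (GM 0.01537, WM 0.03103 MPa) and lower brain
#'     stiffness (GM 0.001389, WM 0.001895 MPa), skull 6000 MPa, densities
#'     1.05e-9 / 1.00e-9 / 3.50e-9, nu 0.45 / 0.4999 / 0.22. The CSF `E`
#'     placeholder is the sweep reference 2.19 MPa.}
#' }
#'
#' @param name preset name.
#' @param nu_cap passed to [material_set()]; default caps nu at 0.49 to
#'   avoid volumetric locking of linear tetrahedra (`NULL` restores the
#'   literature values verbatim).
#' @return a [material_set()].
#' @export
material_presets <- function(name = c("complexity_heterogeneous",
                                      "complexity_homogeneous",
                                      "bc_reference",
                                      "csf_sweep_high", "csf_sweep_low"),
                             nu_cap = 0.49) {
  name <- match.arg(name)
  rho_brain <- 1.05e-9
  switch(name,
    complexity_heterogeneous = material_set(
      WM  = list(E = 0.03103, rho = rho_brain, nu = 0.45),
      GM  = list(E = 0.01537, rho = rho_brain, nu = 0.45),
      CSF = list(E = 0.299,   rho = rho_brain, nu = 0.45),
      nu_cap = nu_cap),
    complexity_homogeneous = material_set(
      WM  = list(E = 0.02320, rho = 1.04e-9, nu = 0.4999),
      GM  = list(E = 0.02320, rho = 1.04e-9, nu = 0.4999),
      CSF = list(E = 0.02320, rho = 1.04e-9, nu = 0.4999),
      HOMOG = list(E = 0.02320, rho = 1.04e-9, nu = 0.4999),
      nu_cap = nu_cap),
    bc_reference = material_set(
      WM    = list(E = 0.497, rho = 1.14e-9, nu = 0.48),
      GM    = list(E = 0.497, rho = 1.14e-9, nu = 0.48),
      CSF   = list(E = 1.314, rho = 1.04e-9, nu = 0.4999),
      SKULL = list(E = 8000,  rho = 4.79e-9, nu = 0.22),
      NECK  = list(E = 8000,  rho = 4.79e-9, nu = 0.22),
      SPINE = list(E = 8000,  rho = 4.79e-9, nu = 0.22),
      nu_cap = nu_cap),
    csf_sweep_high = material_set(
      WM    = list(E = 0.03103, rho = rho_brain, nu = 0.45),
      GM    = list(E = 0.01537, rho = rho_brain, nu = 0.45),
      CSF   = list(E = 2.19,    rho = 1.00e-9, nu = 0.4999),
      SKULL = list(E = 6000,    rho = 3.50e-9, nu = 0.22),
      nu_cap = nu_cap),
    csf_sweep_low = material_set(
      WM    = list(E = 0.001895, rho = rho_brain, nu = 0.45),
      GM    = list(E = 0.001389, rho = rho_brain, nu = 0.45),
      CSF   = list(E = 2.19,     rho = 1.00e-9, nu = 0.4999),
      SKULL = list(E = 6000,     rho = 3.50e-9, nu = 0.22),
      nu_cap = nu_cap))
}

#' CSF Young's modulus grid for the stiffness sweep
#'
#' The literature CSF stiffness values, in MPa, in decreasing order; the
#' first entry (2.19 MPa) is the sweep's reference model.
#' @return numeric vector.
#' @export
csf_stiffness_grid <- function() c(2.19, 1.314, 0.299, 0.1485, 0.012, 0.001)

#' Set one region's Young's modulus
#'
#' @param materials a [material_set()].
#' @param region region label.
#' @param E new Young's modulus (MPa).
#' @return the modified `material_set`.
#' @export
set_region_stiffness <- function(materials, region, E) {
  stopifnot(inherits(materials, "material_set"))
  if (!region %in% names(materials))
    stop("no material defined for region '", region, "'")
  materials[[region]]$E <- as.numeric(E)
  structure(materials, class = "material_set",
            nu_cap = attr(materials, "nu_cap"))
}

#' Read / write a material set as JSON
#'
#' The JSON layout maps each region label to
#' `{"E_MPa": ..., "rho_ton_per_mm3": ..., "nu": ...}`.
#'
#' @param path file path.
#' @param nu_cap passed to [material_set()].
#' @return [read_materials()] returns a [material_set()];
#'   [write_materials()] returns `path` invisibly.
#' @export
read_materials <- function(path, nu_cap = 0.49) {
  raw <- jsonlite::read_json(path)
  args <- lapply(raw, function(m)
    list(E = m$E_MPa, rho = m$rho_ton_per_mm3, nu = m$nu))
  do.call(material_set, c(args, list(nu_cap = nu_cap)))
}

#' @rdname read_materials
#' @param materials a [material_set()] to write.
#' @export
write_materials <- function(materials, path) {
  stopifnot(inherits(materials, "material_set"))
  out <- lapply(materials, function(m)
    list(E_MPa = m$E, rho_ton_per_mm3 = m$rho, nu = m$nu))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.material_set <- function(x, ...) {
  cat("<material_set>  (E in MPa, rho in ton/mm^3)\n")
  for (nm in names(x))
    cat(sprintf("  %-6s E = %-10g rho = %-10g nu = %g\n",
                nm, x[[nm]]$E, x[[nm]]$rho, x[[nm]]$nu))
  invisible(x)
}
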