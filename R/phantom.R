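# Synthetic multi-compartment head phantoms.
#
# The phantom replaces an anatomical mesh with nested quasi-ellipsoidal
# shells (WM core, GM shell, CSF layer, skull shell) that preserve the
# topological layering driving the heterogeneity findings. Meshes are built
# from subdivided-icosahedron surface layers connected radially by
# prism-to-3-tet splits, so construction is deterministic and conforming
# without an external mesher.

#' Phantom configuration
#'
#' @param shell_radii outer radii (mm) of the concentric shells, strictly
#'   increasing. Length 4 gives WM/GM/CSF/SKULL, length 3 WM/GM/CSF,
#'   length 2 WM/GM, length 1 a homogeneous ball (`HOMOG`). The default
#'   places the skull outer surface `skull_thickness` beyond the CSF.
#' @param skull_thickness skull shell thickness in mm (default 5); only used
#'   to derive the default `shell_radii`.
#' @param target_edge_length requested element edge length in mm; controls
#'   both the surface subdivision level and the radial layer count.
#' @param axes length-3 positive scale factors turning the sphere into a
#'   quasi-ellipsoid (x right, y anterior, z superior). `c(1, 1, 1)` gives
#'   spheres; the default is mildly ellipsoidal, which also splits most
#'   eigenvalue degeneracies of the perfect sphere.
#' @param appendage `"none"`, `"neck"` or `"spine"`: attach a compact
#'   cylinder under the skull base (neck default 120 mm, spine 500 mm).
#' @param appendage_length cylinder length in mm; defaults by appendage.
#' @param appendage_radius cylinder radius in mm.
#' @param n_parcels number of gray-matter surface parcels (>= 2) for
#'   mode-to-region projection.
#' @param base_cap_frac fraction of the z-extent (from the bottom) defining
#'   the "base" node set.
#' @param jitter relative amplitude of the seeded node perturbation applied
#'   to split residual symmetric degeneracies (fraction of local radius;
#'   0 disables).
#' @param seed integer seed making the phantom fully deterministic.
#'
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(shell_radii = NULL, skull_thickness = 5,
                           target_edge_length = 14,
                           axes = c(1, 0.85, 0.8),
                           appendage = c("none", "neck", "spine"),
                           appendage_length = NULL, appendage_radius = 25,
                           n_parcels = 16, base_cap_frac = 0.12,
                           jitter = 0.001, seed = 1L) {
  appendage <- match.arg(appendage)
  if (is.null(shell_radii))
    shell_radii <- c(60, 70, 75, 75 + skull_thickness)
  if (any(diff(shell_radii) <= 0) || any(shell_radii <= 0))
    stop("shell_radii must be positive and strictly increasing")
  if (target_edge_length <= 0) stop("target_edge_length must be > 0")
  if (length(axes) != 3 || any(axes <= 0)) stop("axes must be 3 positive scales")
  if (n_parcels < 2) stop("n_parcels must be >= 2")
  if (is.null(appendage_length))
    appendage_length <- switch(appendage, none = 0, neck = 120, spine = 500)
  structure(list(shell_radii = shell_radii,
                 skull_thickness = skull_thickness,
                 target_edge_length = target_edge_length,
                 axes = axes, appendage = appendage,
                 appendage_length = appendage_length,
                 appendage_radius = appendage_radius,
                 n_parcels = as.integer(n_parcels),
                 base_cap_frac = base_cap_frac,
                 jitter = jitter, seed = as.integer(seed)),
            class = "phantom_config")
}

# Region labels implied by the number of shells.
shell_labels <- function(n_shells) {
  switch(n_shells,
         "HOMOG",
         c("WM", "GM"),
         c("WM", "GM", "CSF"),
         c("WM", "GM", "CSF", "SKULL"),
         stop("at most 4 shells are supported"))
}

# --- icosphere ---------------------------------------------------------------

# Unit icosahedron vertices and faces.
icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(1 + t^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

# Subdivide a triangulated sphere surface n times, reprojecting midpoints
# onto the unit sphere. Midpoints are cached so shared edges stay conforming.
icosphere <- function(n_subdiv) {
  s <- icosahedron()
  v <- s$vertices
  f <- s$faces
  for (lev in seq_len(n_subdiv)) {
    cache <- new.env(hash = TRUE, parent = emptyenv())
    nv <- nrow(v)
    extra <- list()
    midpoint <- function(a, b) {
      key <- if (a < b) paste(a, b) else paste(b, a)
      id <- cache[[key]]
      if (!is.null(id)) return(id)
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      nv <<- nv + 1L
      extra[[length(extra) + 1L]] <<- p
      cache[[key]] <- nv
      nv
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[4L * i - 3L, ] <- c(a, ab, ca)
      nf[4L * i - 2L, ] <- c(b, bc, ab)
      nf[4L * i - 1L, ] <- c(c, ca, bc)
      nf[4L * i, ]      <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, extra))
    f <- nf
  }
  list(vertices = v, faces = f)
}

# --- prism splitting ---------------------------------------------------------

# Rotations of a prism (bottom 1,2,3 / top 4,5,6, vertical edges 1-4, 2-5,
# 3-6) bringing each position to the front while preserving the prism
# structure (Dompierre et al. rotation table).
.prism_rot <- rbind(
  c(1, 2, 3, 4, 5, 6),
  c(2, 3, 1, 5, 6, 4),
  c(3, 1, 2, 6, 4, 5),
  c(4, 6, 5, 1, 3, 2),
  c(5, 4, 6, 2, 1, 3),
  c(6, 5, 4, 3, 2, 1))

# Split one prism (6 global node ids) into 3 tetrahedra using the
# min-vertex diagonal rule, which guarantees that the quad-face diagonals
# of neighbouring prisms agree (conforming mesh).
split_prism <- function(p) {
  p <- p[.prism_rot[which.min(p), ]]
  if (min(p[2], p[6]) < min(p[3], p[5]))
    rbind(c(p[1], p[2], p[3], p[6]),
          c(p[1], p[2], p[6], p[5]),
          c(p[1], p[5], p[6], p[4]))
  else
    rbind(c(p[1], p[2], p[3], p[5]),
          c(p[1], p[5], p[3], p[6]),
          c(p[1], p[5], p[6], p[4]))
}

# Split a whole layer of prisms: bottom and top are parallel triangulations
# with identical face connectivity. faces indexes into the per-layer node
# numbering; bot_ids / top_ids map those to global node ids.
split_prism_layer <- function(faces, bot_ids, top_ids) {
  out <- matrix(0L, nrow(faces) * 3L, 4L)
  for (i in seq_len(nrow(faces))) {
    tri <- faces[i, ]
    out[(3L * i - 2L):(3L * i), ] <- split_prism(c(bot_ids[tri], top_ids[tri]))
  }
  out
}

# --- layered phantom ---------------------------------------------------------

#' Build a layered multi-compartment head phantom
#'
#' Generates a conforming tetrahedral mesh of nested quasi-ellipsoidal
#' shells, labels each element by the shell containing its centroid, and
#' attaches the standard boundary node sets:
#' \describe{
#'   \item{base}{outer-surface nodes within `base_cap_frac` of the lowest
#'     z-extent (skull-base fixation).}
#'   \item{base_back_sides}{outer-surface nodes in the bottom z-quantile or
#'     in the back (-y) / side (|x|) sectors, emulating head cushions
#'     during an fMRI exam.}
#'   \item{exterior}{boundary nodes of the mesh after removing skull and
#'     appendage elements, i.e. the brain+CSF outer surface.}
#' }
#' Gray-matter outer-surface nodes are assigned parcel ids by
#' equal-solid-angle angular sectors for mode-to-region projection.
#'
#' @param config a [phantom_config()].
#' @return a [labeled_mesh()]; deterministic for a fixed config.
#' @export
build_layered_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  radii <- config$shell_radii
  labels <- shell_labels(length(radii))
  edge <- config$target_edge_length
  r_out <- radii[length(radii)]

  thickness <- diff(c(0, radii))
  if (any(thickness < edge / 4)) {
    thin <- labels[which.min(thickness)]
    stop("target_edge_length ", edge, " mm is infeasible: shell '", thin,
         "' is only ", min(thickness), " mm thick (needs >= edge/4)")
  }

  # surface subdivision level: icosahedron edge ~ 1.0515 on the unit sphere
  n_sub <- max(1L, ceiling(log2(1.0515 * r_out / edge)))
  surf <- icosphere(n_sub)
  n_surf <- nrow(surf$vertices)

  # radial layer radii, including every shell boundary exactly
  layer_r <- numeric(0)
  prev <- 0
  for (j in seq_along(radii)) {
    n_lay <- max(1L, round(thickness[j] / edge))
    layer_r <- c(layer_r, prev + thickness[j] * seq_len(n_lay) / n_lay)
    prev <- radii[j]
  }
  n_layers <- length(layer_r)

  # nodes: centre + one scaled surface copy per layer
  nodes <- matrix(0, 1 + n_layers * n_surf, 3)
  for (l in seq_len(n_layers)) {
    rows <- 1L + (l - 1L) * n_surf + seq_len(n_surf)
    nodes[rows, ] <- surf$vertices * layer_r[l]
  }
  layer_ids <- function(l) 1L + (l - 1L) * n_surf + seq_len(n_surf)

  # elements: centre fan to layer 1, then prisms between consecutive layers
  tet_list <- vector("list", n_layers)
  ids1 <- layer_ids(1)
  tet_list[[1]] <- cbind(1L, matrix(ids1[t(surf$faces)], ncol = 3, byrow = TRUE))
  for (l in seq_len(n_layers - 1L))
    tet_list[[l + 1L]] <- split_prism_layer(surf$faces,
                                            layer_ids(l), layer_ids(l + 1L))
  tets <- do.call(rbind, tet_list)
  tets <- fix_orientation(tets, nodes)

  # region by centroid radius (before ellipsoidal scaling, radii are literal)
  cent_r <- sqrt(rowSums((
    (nodes[tets[, 1], ] + nodes[tets[, 2], ] +
     nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4)^2))
  region <- labels[findInterval(cent_r, radii, left.open = TRUE) + 1L]

  # apply ellipsoidal scaling
  nodes <- sweep(nodes, 2L, config$axes, `*`)
  tets <- fix_orientation(tets, nodes)

  # node radii in normalized (pre-scaling) units, for surface identification
  norm_r <- c(0, rep(layer_r, each = n_surf))

  # node sets -----------------------------------------------------------
  ext_all <- surface_nodes(tets)                      # full outer surface
  z <- nodes[, 3]
  zr <- range(z[ext_all])
  base <- ext_all[z[ext_all] <= zr[1] + config$base_cap_frac * diff(zr)]

  zq <- stats::quantile(z[ext_all], 0.3)
  xmax <- max(abs(nodes[ext_all, 1]))
  ymin <- min(nodes[ext_all, 2])
  bbs <- ext_all[z[ext_all] <= zq |
                 nodes[ext_all, 2] <= 0.55 * ymin |
                 abs(nodes[ext_all, 1]) >= 0.75 * xmax]

  brain_elems <- which(!region %in% c("SKULL", "NECK", "SPINE"))
  exterior <- surface_nodes(tets, brain_elems)

  node_sets <- list(base = base, base_back_sides = bbs, exterior = exterior)

  # parcels on the GM outer surface -------------------------------------
  parcel <- rep(NA_integer_, nrow(nodes))
  if (length(radii) >= 2) {
    gm_r <- radii[2]
    gm_surf <- which(abs(norm_r - gm_r) < 1e-9 * r_out)
    parcel[gm_surf] <- assign_parcels(nodes[gm_surf, , drop = FALSE],
                                      config$n_parcels)
  }

  # seeded symmetric-degeneracy jitter ----------------------------------
  if (config$jitter > 0) {
    rng <- local_rng(config$seed)
    on.exit(rng(), add = TRUE)
    pert <- matrix(stats::rnorm(length(nodes)), ncol = 3)
    nodes <- nodes + config$jitter * norm_r * pert
    tets <- fix_orientation(tets, nodes)
  }

  mesh <- labeled_mesh(nodes, tets, region, node_sets, parcel)
  if (config$appendage != "none")
    mesh <- attach_cylinder(mesh, config$appendage_length,
                            config$appendage_radius,
                            toupper(config$appendage))
  mesh
}

# Equal-solid-angle parcellation of surface points: bands equal in
# cos(polar angle), azimuthal sectors within each band.
assign_parcels <- function(pts, n_parcels) {
  r <- sqrt(rowSums(pts^2))
  cosb <- pts[, 3] / r
  az <- atan2(pts[, 2], pts[, 1])
  n_bands <- max(1L, round(sqrt(n_parcels)))
  per_band <- rep(n_parcels %/% n_bands, n_bands)
  rem <- n_parcels %% n_bands
  if (rem > 0) per_band[seq_len(rem)] <- per_band[seq_len(rem)] + 1L
  band_edges <- seq(-1, 1, length.out = n_bands + 1L)
  band <- pmin(pmax(findInterval(cosb, band_edges, left.open = TRUE), 1L),
               n_bands)
  offset <- c(0L, cumsum(per_band))
  out <- integer(nrow(pts))
  for (b in seq_len(n_bands)) {
    in_b <- band == b
    k <- per_band[b]
    sec_edges <- seq(-pi, pi, length.out = k + 1L)
    sec <- pmin(pmax(findInterval(az[in_b], sec_edges, left.open = TRUE), 1L), k)
    out[in_b] <- offset[b] + sec
  }
  out
}

# Run code under a fixed RNG seed and restore the caller's RNG state.
# Returns the restore function (call it, or register via on.exit).
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

# --- bar mesh ----------------------------------------------------------------

#' Structured tetrahedral bar for analytic benchmarks
#'
#' A rectangular bar (length along x) on a structured hexahedral grid, each
#' cell split into 6 tetrahedra by the Kuhn/Freudenthal subdivision (exactly
#' space-filling, hence the mesh volume equals `length_mm * side_mm^2`
#' exactly). Node sets `"fixed_end"` (x = 0) and `"free_end"` (x = length)
#' support fixed-free vibration benchmarks.
#'
#' @param length_mm bar length (mm).
#' @param side_mm side of the square cross-section (mm).
#' @param n_divisions number of cells along the length (>= 2); the
#'   cross-section gets `max(2, ceiling(n_divisions * side_mm / length_mm))`
#'   cells per side so elements stay near-isotropic.
#' @return a [labeled_mesh()] with region `"HOMOG"`.
#' @export
build_bar_mesh <- function(length_mm, side_mm, n_divisions) {
  if (n_divisions < 2) stop("n_divisions must be >= 2")
  nx <- as.integer(n_divisions)
  nyz <- max(2L, ceiling(n_divisions * side_mm / length_mm))
  xs <- seq(0, length_mm, length.out = nx + 1L)
  ys <- seq(0, side_mm, length.out = nyz + 1L)
  zs <- ys
  nid <- function(i, j, k)                       # 1-based grid -> node id
    i + (nx + 1L) * ((j - 1L) + (nyz + 1L) * (k - 1L))
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL

  # Kuhn subdivision: 6 tets per cell along vertex-order chains from the
  # cell's lowest corner to its highest; identical in every cell, hence
  # conforming across cell faces.
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cells <- as.matrix(expand.grid(i = seq_len(nx), j = seq_len(nyz),
                                 k = seq_len(nyz)))
  n_cells <- nrow(cells)
  tets <- matrix(0L, n_cells * 6L, 4L)
  ei <- diag(3L)
  row <- 0L
  for (c_i in seq_len(n_cells)) {
    base <- cells[c_i, ]
    for (p in seq_len(6L)) {
      corner <- rbind(base,
                      base + ei[perms[p, 1], ],
                      base + ei[perms[p, 1], ] + ei[perms[p, 2], ],
                      base + 1L)
      row <- row + 1L
      tets[row, ] <- nid(corner[, 1], corner[, 2], corner[, 3])
    }
  }
  tets <- fix_orientation(tets, nodes)
  node_sets <- list(fixed_end = which(nodes[, 1] == 0),
                    free_end = which(nodes[, 1] == length_mm))
  labeled_mesh(nodes, tets, rep("HOMOG", nrow(tets)), node_sets)
}

# --- cylinder attachment -----------------------------------------------------

#' Attach a neck or spine cylinder under the skull base
#'
#' Extrudes the skull boundary faces inside a circular footprint around the
#' inferior pole downward, morphing to a flat base, so the cylinder is
#' conformally joined to the skull (shared nodes, no constraint coupling
#' needed). The far-end nodes form the new node set `"cylinder_base"`.
#'
#' @param mesh a [labeled_mesh()] with a `SKULL` region.
#' @param length_mm cylinder length (mm): 120 for the neck, 500 for the
#'   spine scenarios.
#' @param radius_mm footprint radius around the z axis (mm).
#' @param label region label for the new elements (`"NECK"` or `"SPINE"`).
#' @param n_layers number of extrusion layers; default from the patch's
#'   mean edge length.
#' @return the augmented [labeled_mesh()].
#' @export
attach_cylinder <- function(mesh, length_mm, radius_mm, label = "NECK",
                            n_layers = NULL) {
  if (!"SKULL" %in% mesh$region)
    stop("mesh has no SKULL region to attach a cylinder to")
  bf <- boundary_faces(mesh$tets)
  xy2 <- mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2
  zmid <- mean(range(mesh$nodes[, 3]))
  in_foot <- xy2 <= radius_mm^2 & mesh$nodes[, 3] < zmid
  keep <- in_foot[bf[, 1]] & in_foot[bf[, 2]] & in_foot[bf[, 3]]
  patch <- bf[keep, , drop = FALSE]
  if (nrow(patch) == 0)
    stop("no skull boundary faces inside the attachment footprint ",
         "(radius ", radius_mm, " mm)")

  patch_nodes <- sort(unique(as.vector(patch)))
  local_id <- match(patch, patch_nodes)
  faces_local <- matrix(local_id, ncol = 3)
  p0 <- mesh$nodes[patch_nodes, , drop = FALSE]

  if (is.null(n_layers)) {
    e1 <- sqrt(rowSums((mesh$nodes[patch[, 1], ] - mesh$nodes[patch[, 2], ])^2))
    n_layers <- max(2L, round(length_mm / mean(e1)))
  }
  z_base <- min(p0[, 3]) - length_mm

  n0 <- nrow(mesh$nodes)
  npn <- length(patch_nodes)
  new_nodes <- matrix(0, n_layers * npn, 3)
  for (l in seq_len(n_layers)) {
    t <- l / n_layers
    rows <- (l - 1L) * npn + seq_len(npn)
    new_nodes[rows, 1:2] <- p0[, 1:2]
    new_nodes[rows, 3] <- (1 - t) * p0[, 3] + t * z_base
  }
  nodes <- rbind(mesh$nodes, new_nodes)
  lay_ids <- function(l) if (l == 0L) patch_nodes else
    n0 + (l - 1L) * npn + seq_len(npn)

  new_tets <- do.call(rbind, lapply(seq_len(n_layers), function(l)
    split_prism_layer(faces_local, lay_ids(l - 1L), lay_ids(l))))
  new_tets <- fix_orientation(new_tets, nodes)

  tets <- rbind(mesh$tets, new_tets)
  region <- c(mesh$region, rep(label, nrow(new_tets)))
  node_sets <- mesh$node_sets
  node_sets$cylinder_base <- lay_ids(n_layers)
  parcel <- c(mesh$parcel, rep(NA_integer_, nrow(new_nodes)))
  out <- labeled_mesh(nodes, tets, region, node_sets, parcel)
  attr(out, "node_origin") <- attr(mesh, "node_origin")
  out
}

# --- skull stripping ---------------------------------------------------------

#' Remove the skull (and appendages) from a phantom
#'
#' Drops `SKULL`, `NECK` and `SPINE` elements, compacts the node numbering,
#' and recomputes the `"exterior"` node set on the new outer surface. The
#' original node index of each surviving node is recorded in the
#' `"node_origin"` attribute so modal results on the stripped mesh can be
#' compared with full-mesh results on the shared brain nodes.
#'
#' @param mesh a [labeled_mesh()].
#' @return the stripped [labeled_mesh()]; a no-op (with a warning) if there
#'   is no skull.
#' @export
strip_skull <- function(mesh) {
  drop_regions <- c("SKULL", "NECK", "SPINE")
  if (!any(mesh$region %in% drop_regions)) {
    warning("mesh has no skull to strip; returning unchanged")
    return(mesh)
  }
  keep_el <- !(mesh$region %in% drop_regions)
  tets <- mesh$tets[keep_el, , drop = FALSE]
  keep_nodes <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(mesh$nodes))
  remap[keep_nodes] <- seq_along(keep_nodes)
  tets <- matrix(remap[tets], ncol = 4)

  node_sets <- lapply(mesh$node_sets, function(s) remap[s[s %in% keep_nodes]])
  node_sets <- node_sets[lengths(node_sets) > 0]
  out <- labeled_mesh(mesh$nodes[keep_nodes, , drop = FALSE], tets,
                      mesh$region[keep_el], node_sets,
                      mesh$parcel[keep_nodes])
  out$node_sets$exterior <- surface_nodes(out$tets)
  origin <- attr(mesh, "node_origin")
  attr(out, "node_origin") <-
    if (is.null(origin)) keep_nodes else origin[keep_nodes]
  validate_mesh(out)
  out
}
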