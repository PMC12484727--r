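#' Labeled tetrahedral mesh
#'
#' The geometric substrate used throughout the package: a tetrahedral mesh
#' with a region label per element and named node sets for boundary
#' conditions. Coordinates are in millimetres; node and element indices are
#' 1-based (the R convention, and the convention of the Abaqus `.inp`
#' dialect written by [write_mesh()]).
#'
#' @param nodes numeric matrix, one row per node, columns x, y, z (mm).
#' @param tets integer matrix, one row per element, the 4 node indices.
#'   Every element must have strictly positive signed volume; use
#'   [fix_orientation()] if the source ordering is unknown.
#' @param region character or factor, one region label per element. Standard
#'   labels are `"WM"`, `"GM"`, `"CSF"`, `"SKULL"`, `"NECK"`, `"SPINE"`,
#'   `"HOMOG"`, but any label a [material_set()] can name is allowed.
#' @param node_sets named list of integer vectors (node indices), e.g.
#'   `"base"`, `"exterior"`, `"cylinder_base"`.
#' @param parcel optional integer vector, one entry per node: parcel id for
#'   gray-matter surface nodes, `NA` elsewhere. Used by
#'   [project_mode_to_parcels()].
#' @param validate if `TRUE` (default) check the invariants.
#'
#' @return an object of class `labeled_mesh`.
#' @export
labeled_mesh <- function(nodes, tets, region, node_sets = list(),
                         parcel = NULL, validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  region <- as.character(region)
  if (is.null(parcel)) parcel <- rep(NA_integer_, nrow(nodes))
  mesh <- structure(
    list(nodes = nodes, tets = tets, region = region,
         node_sets = node_sets, parcel = as.integer(parcel)),
    class = "labeled_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate the invariants of a labeled mesh
#'
#' Checks that all referenced node indices exist, every element has exactly
#' one region label, every tetrahedron has strictly positive signed volume,
#' and parcel labels have one entry per node.
#'
#' @param mesh a [labeled_mesh()].
#' @return the mesh, invisibly; stops with an informative error otherwise.
#' @export
validate_mesh <- function(mesh) {
  n <- nrow(mesh$nodes)
  if (ncol(mesh$nodes) != 3L) stop("nodes must have 3 coordinate columns")
  if (ncol(mesh$tets) != 4L) stop("tets must have 4 node-index columns")
  idx <- range(mesh$tets)
  if (idx[1] < 1L || idx[2] > n)
    stop("tets reference node indices outside 1..", n)
  if (length(mesh$region) != nrow(mesh$tets))
    stop("region must have one label per element")
  for (nm in names(mesh$node_sets)) {
    s <- mesh$node_sets[[nm]]
    if (length(s) && (min(s) < 1L || max(s) > n))
      stop("node set '", nm, "' references node indices outside 1..", n)
  }
  if (length(mesh$parcel) != n)
    stop("parcel must have one entry per node")
  v <- tet_volumes(mesh)
  if (any(v <= 0)) {
    bad <- which(v <= 0)[1]
    stop("element ", bad, " has non-positive signed volume (", v[bad], ")")
  }
  invisible(mesh)
}

#' Signed volumes of all tetrahedra
#'
#' @param mesh a [labeled_mesh()], or a node-coordinate matrix if `tets`
#'   is given separately.
#' @param tets optional element matrix when `mesh` is a coordinate matrix.
#' @return numeric vector of signed volumes (mm^3); positive under the
#'   package's vertex-ordering convention.
#' @export
tet_volumes <- function(mesh, tets = NULL) {
  if (inherits(mesh, "labeled_mesh")) {
    nodes <- mesh$nodes; tets <- mesh$tets
  } else nodes <- mesh
  a <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - a
  e2 <- nodes[tets[, 3], , drop = FALSE] - a
  e3 <- nodes[tets[, 4], , drop = FALSE] - a
  # triple product e1 . (e2 x e3), vectorized over elements
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) +
   e1[, 2] * (e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]) +
   e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
}

#' Reorder tetrahedra so every signed volume is positive
#'
#' Swaps the last two vertices of any negatively oriented element. Vertex
#' swaps within an element do not change the mesh geometry or face
#' structure, only the orientation convention.
#'
#' @param tets element matrix.
#' @param nodes node-coordinate matrix.
#' @return element matrix with all positive signed volumes.
#' @export
fix_orientation <- function(tets, nodes) {
  v <- tet_volumes(nodes, tets)
  neg <- v < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  tets
}

#' Total mesh volume, optionally per region
#'
#' @param mesh a [labeled_mesh()].
#' @param by_region if `TRUE`, return a named vector of per-region volumes.
#' @return total volume in mm^3, or a named vector.
#' @export
mesh_volume <- function(mesh, by_region = FALSE) {
  v <- tet_volumes(mesh)
  if (by_region) tapply(v, mesh$region, sum) else sum(v)
}

#' Boundary faces of a tetrahedral mesh
#'
#' A triangular face is on the boundary iff it appears in exactly one
#' tetrahedron. This is the package's surface-extraction primitive, used to
#' compute "exterior" node sets and cylinder attachment footprints.
#'
#' @param tets element matrix (or a [labeled_mesh()]).
#' @param elements optional integer vector restricting the extraction to a
#'   subset of elements (e.g. one region).
#' @return integer matrix of boundary faces (3 node indices per row, sorted
#'   within each row), with attribute `"elem"` giving the owning element id.
#' @export
boundary_faces <- function(tets, elements = NULL) {
  if (inherits(tets, "labeled_mesh")) tets <- tets$tets
  if (!is.null(elements)) tets <- tets[elements, , drop = FALSE]
  m <- nrow(tets)
  faces <- rbind(tets[, c(1, 2, 3), drop = FALSE],
                 tets[, c(1, 2, 4), drop = FALSE],
                 tets[, c(1, 3, 4), drop = FALSE],
                 tets[, c(2, 3, 4), drop = FALSE])
  elem <- rep.int(seq_len(m), 4L)
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  key <- paste(lo, mid, hi)
  cnt <- table(key)
  on_boundary <- cnt[key] == 1L
  out <- cbind(lo, mid, hi)[on_boundary, , drop = FALSE]
  colnames(out) <- NULL
  if (!is.null(elements)) elem <- elements[elem]
  attr(out, "elem") <- elem[on_boundary]
  out
}

#' Nodes on the boundary surface
#'
#' @inheritParams boundary_faces
#' @return sorted integer vector of node indices lying on boundary faces.
#' @export
surface_nodes <- function(tets, elements = NULL) {
  sort(unique(as.vector(boundary_faces(tets, elements))))
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat("<labeled_mesh>\n")
  cat("  nodes:   ", nrow(x$nodes), "\n")
  cat("  elements:", nrow(x$tets), "\n")
  tab <- table(x$region)
  cat("  regions: ", paste(sprintf("%s (%d)", names(tab), tab),
                           collapse = ", "), "\n")
  if (length(x$node_sets))
    cat("  node sets:", paste(sprintf("%s (%d)", names(x$node_sets),
                                      lengths(x$node_sets)),
                              collapse = ", "), "\n")
  np <- sum(!is.na(x$parcel))
  if (np) cat("  parcel-labeled nodes:", np, "in",
              length(unique(stats::na.omit(x$parcel))), "parcels\n")
  invisible(x)
}
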