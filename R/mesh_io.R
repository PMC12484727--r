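# Mesh readers/writers: an Abaqus-.inp dialect (round-trip format) and
# legacy ASCII VTK (visualization export).
#
# The .inp dialect uses 1-based node/element ids, *NODE, *ELEMENT
# (TYPE=C3D4) with one *ELSET per region, one *NSET per node set, and
# PARCEL_<k> node sets carrying the gray-matter parcel labels.

#' Write a labeled mesh to disk
#'
#' @param mesh a [labeled_mesh()].
#' @param path output file path.
#' @param format `"inp"` (Abaqus dialect; lossless round trip via
#'   [read_mesh()]) or `"vtk"` (legacy ASCII unstructured grid with the
#'   region label as cell data and the parcel id as point data).
#' @param point_data optional named list of per-node vector fields
#'   (matrices `n_nodes x 3`) added to a VTK file, e.g. mode shapes.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("inp", "vtk"),
                       point_data = NULL) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  format <- match.arg(format)
  if (format == "inp") write_mesh_inp(mesh, path) else
    write_mesh_vtk(mesh, path, point_data)
  invisible(path)
}

write_mesh_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(..., con = con)
  wl("*HEADING")
  wl("Layered phantom mesh (brainmodes package); units mm, ids 1-based")
  wl("*NODE")
  wl(sprintf("%d, %.17g, %.17g, %.17g", seq_len(nrow(mesh$nodes)),
             mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]))
  eid <- seq_len(nrow(mesh$tets))
  for (r in unique(mesh$region)) {
    sel <- mesh$region == r
    wl(sprintf("*ELEMENT, TYPE=C3D4, ELSET=%s", r))
    wl(sprintf("%d, %d, %d, %d, %d", eid[sel], mesh$tets[sel, 1],
               mesh$tets[sel, 2], mesh$tets[sel, 3], mesh$tets[sel, 4]))
  }
  write_id_block <- function(header, ids) {
    wl(header)
    for (start in seq(1, length(ids), by = 16L))
      wl(paste(ids[start:min(start + 15L, length(ids))], collapse = ", "))
  }
  for (nm in names(mesh$node_sets))
    write_id_block(sprintf("*NSET, NSET=%s", nm), mesh$node_sets[[nm]])
  labeled <- which(!is.na(mesh$parcel))
  if (length(labeled))
    for (p in sort(unique(mesh$parcel[labeled])))
      write_id_block(sprintf("*NSET, NSET=PARCEL_%d", p),
                     which(!is.na(mesh$parcel) & mesh$parcel == p))
  invisible(path)
}

write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(..., con = con)
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  regions <- sort(unique(mesh$region))
  wl("# vtk DataFile Version 3.0")
  wl(paste("brainmodes mesh; regions:",
           paste(sprintf("%d=%s", seq_along(regions) - 1L, regions),
                 collapse = " ")))
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", n))
  wl(sprintf("%.17g %.17g %.17g", mesh$nodes[, 1], mesh$nodes[, 2],
             mesh$nodes[, 3]))
  wl(sprintf("CELLS %d %d", m, 5L * m))
  wl(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
             mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L))
  wl(sprintf("CELL_TYPES %d", m))
  wl(as.character(rep(10L, m)))
  wl(sprintf("CELL_DATA %d", m))
  wl("SCALARS region int 1")
  wl("LOOKUP_TABLE default")
  wl(as.character(match(mesh$region, regions) - 1L))
  wl(sprintf("POINT_DATA %d", n))
  wl("SCALARS parcel int 1")
  wl("LOOKUP_TABLE default")
  parcel <- mesh$parcel
  parcel[is.na(parcel)] <- -1L
  wl(as.character(parcel))
  for (nm in names(point_data)) {
    v <- point_data[[nm]]
    wl(sprintf("VECTORS %s double", nm))
    wl(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]))
  }
  invisible(path)
}

#' Read a labeled mesh
#'
#' Reads the Abaqus-.inp dialect written by [write_mesh()] (also accepting
#' hand-written files with `*NODE`, `*ELEMENT TYPE=C3D4` + `ELSET`, and
#' `*NSET` blocks), or the package's legacy-VTK export. Malformed files
#' fail with the offending line number.
#'
#' @param path input file; format detected from the first line (`# vtk`
#'   prefix) unless `format` is given.
#' @param format `"inp"`, `"vtk"` or `NULL` (autodetect).
#' @return a [labeled_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(format))
    format <- if (startsWith(first, "# vtk")) "vtk" else "inp"
  if (format == "vtk") read_mesh_vtk(path) else read_mesh_inp(path)
}

read_mesh_inp <- function(path) {
  lines <- readLines(path)
  n_lines <- length(lines)
  nodes_id <- integer(0); nodes_xyz <- list()
  elem_id <- integer(0); elem_conn <- list(); elem_region <- character(0)
  node_sets <- list()
  fail <- function(i, msg) stop("malformed .inp at line ", i, ": ", msg)

  mode <- "none"; current_name <- NULL
  for (i in seq_len(n_lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "**")) next
    if (startsWith(ln, "*")) {
      up <- toupper(ln)
      if (startsWith(up, "*HEADING")) { mode <- "heading" }
      else if (startsWith(up, "*NODE")) { mode <- "node" }
      else if (startsWith(up, "*ELEMENT")) {
        kv <- parse_inp_keywords(ln)
        if (!identical(toupper(kv[["TYPE"]]), "C3D4"))
          fail(i, "only TYPE=C3D4 elements are supported")
        current_name <- if (!is.null(kv[["ELSET"]])) kv[["ELSET"]] else "HOMOG"
        mode <- "element"
      }
      else if (startsWith(up, "*NSET")) {
        kv <- parse_inp_keywords(ln)
        if (is.null(kv[["NSET"]])) fail(i, "*NSET without NSET= name")
        current_name <- kv[["NSET"]]
        node_sets[[current_name]] <- integer(0)
        mode <- "nset"
      }
      else mode <- "skip"
      next
    }
    vals <- strsplit(ln, ",")[[1]]
    if (mode == "node") {
      if (length(vals) != 4) fail(i, "node lines need 'id, x, y, z'")
      num <- suppressWarnings(as.numeric(vals))
      if (any(is.na(num))) fail(i, "non-numeric node data")
      nodes_id <- c(nodes_id, as.integer(num[1]))
      nodes_xyz[[length(nodes_xyz) + 1L]] <- num[2:4]
    } else if (mode == "element") {
      if (length(vals) != 5) fail(i, "C3D4 lines need 'id, n1, n2, n3, n4'")
      num <- suppressWarnings(as.integer(vals))
      if (any(is.na(num))) fail(i, "non-integer element data")
      elem_id <- c(elem_id, num[1])
      elem_conn[[length(elem_conn) + 1L]] <- num[2:5]
      elem_region <- c(elem_region, current_name)
    } else if (mode == "nset") {
      num <- suppressWarnings(as.integer(vals[nzchar(trimws(vals))]))
      if (any(is.na(num))) fail(i, "non-integer node set data")
      node_sets[[current_name]] <- c(node_sets[[current_name]], num)
    }
  }
  if (length(nodes_id) == 0) stop("no *NODE block found in ", path)
  if (length(elem_id) == 0) stop("no *ELEMENT block found in ", path)

  ord <- order(nodes_id)
  nodes <- do.call(rbind, nodes_xyz)[ord, , drop = FALSE]
  id_map <- integer(max(nodes_id))
  id_map[nodes_id[ord]] <- seq_along(nodes_id)
  eord <- order(elem_id)
  tets <- matrix(id_map[do.call(rbind, elem_conn)[eord, , drop = FALSE]],
                 ncol = 4)
  region <- elem_region[eord]

  parcel <- rep(NA_integer_, nrow(nodes))
  is_parcel <- grepl("^PARCEL_[0-9]+$", names(node_sets))
  for (nm in names(node_sets)[is_parcel]) {
    p <- as.integer(sub("^PARCEL_", "", nm))
    parcel[id_map[node_sets[[nm]]]] <- p
  }
  node_sets <- lapply(node_sets[!is_parcel],
                      function(s) as.integer(sort(id_map[s])))
  labeled_mesh(nodes, tets, region, node_sets, parcel)
}

parse_inp_keywords <- function(line) {
  parts <- strsplit(line, ",")[[1]][-1]
  kv <- list()
  for (p in parts) {
    eq <- strsplit(p, "=")[[1]]
    if (length(eq) == 2) kv[[toupper(trimws(eq[1]))]] <- trimws(eq[2])
  }
  kv
}

read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  header <- lines[2]
  regions <- NULL
  if (grepl("regions:", header)) {
    spec <- sub(".*regions:\\s*", "", header)
    kv <- strsplit(strsplit(spec, "\\s+")[[1]], "=")
    regions <- vapply(kv, `[`, "", 2)
    names(regions) <- vapply(kv, `[`, "", 1)
  }
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stop("malformed VTK: no POINTS block")
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  nodes <- matrix(scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cells <- matrix(scan(text = lines[(ic + 1):(ic + m)], quiet = TRUE),
                  ncol = 5, byrow = TRUE)
  tets <- cells[, 2:5, drop = FALSE] + 1L
  ird <- grep("^SCALARS region", lines)[1]
  region_code <- if (!is.na(ird))
    scan(text = lines[(ird + 2):(ird + 1 + m)], quiet = TRUE)
  else rep(0L, m)
  region <- if (!is.null(regions)) unname(regions[as.character(region_code)])
  else as.character(region_code)
  ipd <- grep("^SCALARS parcel", lines)[1]
  parcel <- if (!is.na(ipd)) {
    p <- as.integer(scan(text = lines[(ipd + 2):(ipd + 1 + n)], quiet = TRUE))
    p[p < 0] <- NA_integer_
    p
  } else NULL
  labeled_mesh(nodes, tets, region, list(), parcel)
}
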