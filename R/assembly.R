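# Global stiffness/mass assembly for heterogeneous isotropic linear
# elasticity on linear (constant-strain) tetrahedra, and Dirichlet
# constraint elimination.
#
# DOF numbering: node i owns DOFs 3i-2 (x), 3i-1 (y), 3i (z).

#' Isotropic elasticity matrix (engineering/Voigt notation)
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio.
#' @return 6x6 matrix relating strain (xx, yy, zz, xy, yz, xz) to stress,
#'   with shear modulus `mu = E / (2 (1 + nu))` on the shear diagonal.
#' @export
elasticity_matrix <- function(E, nu) {
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lambda
  diag(D)[1:3] <- lambda + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# Shape-function gradients of a linear tetrahedron: 4x3 matrix, row i is
# grad N_i (constant over the element). Also returns the volume.
tet_gradients <- function(coords) {
  A <- cbind(1, coords)
  V <- det(A) / 6
  if (V <= 0) stop("degenerate or negatively oriented tetrahedron")
  C <- solve(A)                   # rows: 1, x, y, z coefficients
  list(grads = t(C[2:4, , drop = FALSE]), volume = V)
}

#' Element stiffness matrix of a linear tetrahedron
#'
#' `K_e = V B^T D B` with the constant strain-displacement operator `B`
#' of the 4-node tetrahedron and the isotropic elasticity matrix `D`.
#' Symmetric positive semi-definite with the 6-dimensional rigid-body null
#' space (3 translations, 3 infinitesimal rotations).
#'
#' @param coords 4x3 node coordinates (mm), positively oriented.
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio.
#' @return 12x12 symmetric matrix (DOF order x1,y1,z1,...,x4,y4,z4).
#' @export
element_stiffness <- function(coords, E, nu) {
  g <- tet_gradients(coords)
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    b <- g$grads[i, 1]; c_ <- g$grads[i, 2]; d <- g$grads[i, 3]
    col <- 3 * (i - 1)
    B[1, col + 1] <- b
    B[2, col + 2] <- c_
    B[3, col + 3] <- d
    B[4, col + 1] <- c_; B[4, col + 2] <- b
    B[5, col + 2] <- d;  B[5, col + 3] <- c_
    B[6, col + 1] <- d;  B[6, col + 3] <- b
  }
  g$volume * t(B) %*% elasticity_matrix(E, nu) %*% B
}

#' Consistent element mass matrix of a linear tetrahedron
#'
#' Node-pair blocks `(rho V / 20) (1 + delta_ij) I3`; positive definite and
#' mass-conserving (entries per coordinate direction sum to `rho V`).
#'
#' @param coords 4x3 node coordinates (mm).
#' @param rho density (ton/mm^3).
#' @param lumped if `TRUE`, return the row-sum lumped (diagonal) mass
#'   `rho V / 4` per node instead.
#' @return 12x12 symmetric matrix.
#' @export
element_mass <- function(coords, rho, lumped = FALSE) {
  V <- tet_gradients(coords)$volume
  if (lumped) return(diag(rep(rho * V / 4, 12)))
  Mn <- matrix(rho * V / 20, 4, 4)
  diag(Mn) <- rho * V / 10
  kronecker(Mn, diag(3))
}

#' Assemble the global stiffness and mass matrices
#'
#' Standard scatter-add of element matrices over all tetrahedra, 3 DOFs per
#' node, using a closed-form vectorized evaluation of the isotropic CST
#' stiffness `K_ab = V (lambda g_a g_b^T + mu g_b g_a^T + mu (g_a.g_b) I)`
#' (verified against [element_stiffness()] in the test suite).
#'
#' @param mesh a [labeled_mesh()].
#' @param materials a [material_set()] covering every region label in the
#'   mesh.
#' @param mass `"consistent"` (default) or `"lumped"` element mass.
#' @return an object of class `assembled_system`: sparse symmetric `K`
#'   (N/mm) and `M` (ton), the free-DOF index vector `free_dofs`
#'   (unconstrained: all DOFs), `n_free`, `n_nodes`, and `mass` tag.
#' @export
assemble <- function(mesh, materials, mass = c("consistent", "lumped")) {
  mass <- match.arg(mass)
  stopifnot(inherits(mesh, "labeled_mesh"),
            inherits(materials, "material_set"))
  missing_mat <- setdiff(unique(mesh$region), names(materials))
  if (length(missing_mat))
    stop("no material defined for region(s): ",
         paste(missing_mat, collapse = ", "))

  tets <- mesh$tets
  nodes <- mesh$nodes
  ne <- nrow(tets)
  n_dof <- 3L * nrow(nodes)

  # per-element material constants
  lam <- mu <- rho <- numeric(ne)
  for (r in unique(mesh$region)) {
    m <- materials[[r]]
    sel <- mesh$region == r
    lam[sel] <- m$E * m$nu / ((1 + m$nu) * (1 - 2 * m$nu))
    mu[sel] <- m$E / (2 * (1 + m$nu))
    rho[sel] <- m$rho
  }

  # vectorized shape-function gradients: for vertices a,b,c,d with edges
  # e1=b-a, e2=c-a, e3=d-a and V6 = det(e1,e2,e3),
  # grad N_b = (e2 x e3)/V6, grad N_c = (e3 x e1)/V6, grad N_d = (e1 x e2)/V6
  a <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - a
  e2 <- nodes[tets[, 3], , drop = FALSE] - a
  e3 <- nodes[tets[, 4], , drop = FALSE] - a
  cross <- function(u, v)
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  c23 <- cross(e2, e3)
  V6 <- rowSums(e1 * c23)
  if (any(V6 <= 0))
    stop("degenerate element(s): ", paste(utils::head(which(V6 <= 0)),
                                          collapse = ", "))
  V <- V6 / 6
  g <- vector("list", 4)            # g[[i]]: ne x 3 gradient of N_i
  g[[2]] <- c23 / V6
  g[[3]] <- cross(e3, e1) / V6
  g[[4]] <- cross(e1, e2) / V6
  g[[1]] <- -(g[[2]] + g[[3]] + g[[4]])

  # triplets: 16 node-pair blocks x 9 entries, vectorized over elements
  n_trip <- ne * 144L
  ii <- integer(n_trip); jj <- integer(n_trip)
  kx <- numeric(n_trip); mx <- numeric(n_trip)
  dof <- function(node_col, r) 3L * (tets[, node_col] - 1L) + r
  pos <- 0L
  for (na in 1:4) for (nb in 1:4) {
    ga <- g[[na]]; gb <- g[[nb]]
    dot_ab <- rowSums(ga * gb)
    mass_ab <- if (mass == "consistent")
      rho * V / 20 * (1 + (na == nb)) else
      if (na == nb) rho * V / 4 else numeric(ne)
    for (r in 1:3) for (s in 1:3) {
      idx <- pos + seq_len(ne)
      ii[idx] <- dof(na, r)
      jj[idx] <- dof(nb, s)
      kx[idx] <- V * (lam * ga[, r] * gb[, s] + mu * gb[, r] * ga[, s] +
                      if (r == s) mu * dot_ab else 0)
      mx[idx] <- if (r == s) mass_ab else 0
      pos <- pos + ne
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = kx, dims = c(n_dof, n_dof))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = mx, dims = c(n_dof, n_dof))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  M <- Matrix::forceSymmetric((M + Matrix::t(M)) / 2)

  structure(list(K = K, M = M, free_dofs = seq_len(n_dof),
                 n_free = n_dof, n_nodes = nrow(nodes), mass = mass,
                 constrained = FALSE),
            class = "assembled_system")
}

#' Apply zero-displacement (Dirichlet) boundary conditions by elimination
#'
#' Removes the rows and columns of the constrained DOFs (exact elimination,
#' not a penalty), keeping `K` and `M` symmetric and `M` positive definite
#' on the free DOFs. "Fixed" means all three translational DOFs unless
#' `directions` says otherwise.
#'
#' @param system an [assemble()]d system (unconstrained).
#' @param mesh the generating [labeled_mesh()].
#' @param node_set_name name of a node set in `mesh`, or an integer vector
#'   of node indices.
#' @param directions subset of `1:3` (x, y, z) to fix at those nodes.
#' @return a reduced `assembled_system`; `free_dofs` maps reduced indices
#'   to original DOF indices. Fixing every DOF is an error (no dynamics
#'   left); an empty node set is an error (it would silently leave
#'   rigid-body modes).
#' @export
apply_dirichlet <- function(system, mesh, node_set_name, directions = 1:3) {
  stopifnot(inherits(system, "assembled_system"))
  if (system$constrained)
    stop("system is already constrained; apply all constraints in one call")
  nodes_fix <- if (is.character(node_set_name)) {
    s <- mesh$node_sets[[node_set_name]]
    if (is.null(s)) stop("node set '", node_set_name, "' not found")
    s
  } else as.integer(node_set_name)
  if (length(nodes_fix) == 0)
    stop("empty node set: would leave rigid-body modes unconstrained")
  fixed <- as.vector(outer(as.integer(directions),
                           3L * (nodes_fix - 1L), `+`))
  free <- setdiff(seq_len(3L * system$n_nodes), fixed)
  if (length(free) == 0)
    stop("fully constrained: no free DOFs remain")
  structure(list(K = system$K[free, free], M = system$M[free, free],
                 free_dofs = free, n_free = length(free),
                 n_nodes = system$n_nodes, mass = system$mass,
                 constrained = TRUE),
            class = "assembled_system")
}

#' @export
print.assembled_system <- function(x, ...) {
  cat("<assembled_system>\n")
  cat("  nodes:", x$n_nodes, "  DOFs:", 3 * x$n_nodes,
      "  free:", x$n_free, "\n")
  cat("  mass formulation:", x$mass, "\n")
  cat("  nnz(K):", length(x$K@x), "\n")
  invisible(x)
}
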