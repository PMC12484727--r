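# Quantitative comparison of modal results: MAC matrices, optimal mode
# pairing, and the normalized relative frequency difference (NRFD).

#' Modal Assurance Criterion between two mode vectors
#'
#' `MAC = (phi_A^T phi_B)^2 / ((phi_A^T phi_A)(phi_B^T phi_B))`: the squared
#' normalized dot product, in `[0, 1]`, with 1 for perfect consistency.
#' Invariant to scaling and sign of either vector.
#'
#' @param phi_a,phi_b numeric vectors of equal length on the same DOF
#'   basis, both nonzero. (Comparing modes from different meshes is
#'   unsupported: restrict both to shared DOFs first, as
#'   [compare_on_common_nodes()] does.)
#' @return MAC value in `[0, 1]`.
#' @export
mac <- function(phi_a, phi_b) {
  if (length(phi_a) != length(phi_b))
    stop("mode vectors have different lengths (", length(phi_a), " vs ",
         length(phi_b), "); MAC requires a shared DOF basis")
  na2 <- sum(phi_a^2); nb2 <- sum(phi_b^2)
  if (na2 == 0 || nb2 == 0) stop("MAC is undefined for a zero vector")
  min(1, sum(phi_a * phi_b)^2 / (na2 * nb2))
}

#' MAC matrix between two mode sets
#'
#' @param A,B `modal_result` objects on the same DOF space, or plain
#'   matrices with one mode per column.
#' @return `n_A x n_B` matrix with entry `(i, k) = mac(phi_iA, phi_kB)`.
#' @export
mac_matrix <- function(A, B) {
  SA <- if (inherits(A, "modal_result")) A$shapes else as.matrix(A)
  SB <- if (inherits(B, "modal_result")) B$shapes else as.matrix(B)
  if (nrow(SA) != nrow(SB))
    stop("mode sets live on different DOF spaces (", nrow(SA), " vs ",
         nrow(SB), " DOFs)")
  if (any(colSums(SA^2) == 0) || any(colSums(SB^2) == 0))
    stop("MAC is undefined for a zero vector")
  num <- crossprod(SA, SB)^2
  den <- outer(colSums(SA^2), colSums(SB^2))
  pmin(num / den, 1)
}

#' Optimal one-to-one mode pairing from a MAC matrix
#'
#' Solves the linear assignment problem maximizing total MAC (Hungarian
#' algorithm), then drops pairs whose MAC falls below `threshold`.
#' Deterministic: ties are broken towards ascending mode index.
#'
#' @param mac_mat MAC matrix (rows: set A, columns: set B).
#' @param threshold minimum MAC for a pair to be retained (default 0.5).
#' @return list with `pairs` (data.frame `i`, `k`, `mac`, sorted by `i`),
#'   `unpaired_a`, `unpaired_b` (index vectors).
#' @export
pair_modes <- function(mac_mat, threshold = 0.5) {
  mac_mat <- as.matrix(mac_mat)
  if (!all(is.finite(mac_mat))) stop("MAC matrix must be finite")
  na <- nrow(mac_mat); nb <- ncol(mac_mat)
  assign_ab <- solve_assignment(-mac_mat)   # minimizes cost = -MAC
  i <- which(!is.na(assign_ab))
  k <- assign_ab[i]
  macs <- mac_mat[cbind(i, k)]
  keep <- macs >= threshold
  pairs <- data.frame(i = i[keep], k = k[keep], mac = macs[keep])
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unpaired_a = setdiff(seq_len(na), pairs$i),
       unpaired_b = setdiff(seq_len(nb), pairs$k))
}

# Hungarian algorithm (Jonker-Volgenant style shortest augmenting path,
# O(n^3)) minimizing total cost. Rectangular matrices are padded to square
# with zero-cost dummies. Returns, per row, the assigned column (NA for
# rows matched to a dummy column).
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  n <- max(nr, nc)
  a <- matrix(0, n, n)
  a[seq_len(nr), seq_len(nc)] <- cost
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)          # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L                   # column indices offset by +1 (1 = virtual)
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (!used[j]) {
          cur <- a[i0, j - 1L] - u[i0 + 0L] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1L:(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  out <- rep(NA_integer_, nr)
  for (j in 2L:(n + 1L)) {
    row <- p[j]; col <- j - 1L
    if (row >= 1 && row <= nr && col <= nc) out[row] <- col
  }
  out
}

#' Normalized Relative Frequency Difference
#'
#' `NRFD = |f_r - f_v| / f_r` between the natural frequencies of a
#' reference model (`f_r`) and a validation model (`f_v`): 0 for no
#' difference, 1 for complete discrepancy. Vectorized.
#'
#' @param f_r reference frequencies (> 0).
#' @param f_v validation frequencies.
#' @param percent if `TRUE`, return percentages instead of fractions.
#' @return numeric vector of NRFD values (>= 0).
#' @export
nrfd <- function(f_r, f_v, percent = FALSE) {
  if (any(f_r <= 0)) stop("reference frequencies must be > 0")
  out <- abs(f_r - f_v) / f_r
  if (percent) 100 * out else out
}

#' Full comparison of two modal results
#'
#' Composes [mac_matrix()], [pair_modes()] and [nrfd()] per matched pair.
#'
#' @param A reference `modal_result` (its frequencies are the NRFD
#'   denominator), or a shape matrix plus `f_a`.
#' @param B validation `modal_result`, or a shape matrix plus `f_b`.
#' @param threshold MAC pairing threshold (default 0.5).
#' @param f_a,f_b frequencies when `A` / `B` are plain matrices.
#' @return an object of class `mode_comparison`: `mac` matrix, `pairs`
#'   data.frame (`i`, `k`, `mac`, `f_ref`, `f_val`, `nrfd`),
#'   `unpaired_a`, `unpaired_b`, `threshold`.
#' @export
compare_modes <- function(A, B, threshold = 0.5, f_a = NULL, f_b = NULL) {
  if (inherits(A, "modal_result")) f_a <- A$frequencies_hz
  if (inherits(B, "modal_result")) f_b <- B$frequencies_hz
  mm <- mac_matrix(A, B)
  pr <- pair_modes(mm, threshold)
  pairs <- pr$pairs
  if (!is.null(f_a) && !is.null(f_b) && nrow(pairs)) {
    pairs$f_ref <- f_a[pairs$i]
    pairs$f_val <- f_b[pairs$k]
    pairs$nrfd <- nrfd(pairs$f_ref, pairs$f_val)
  }
  structure(list(mac = mm, pairs = pairs, unpaired_a = pr$unpaired_a,
                 unpaired_b = pr$unpaired_b, threshold = threshold),
            class = "mode_comparison")
}

#' Restrict two modal results to shared nodes and compare
#'
#' Scenarios on different meshes of the same phantom family (e.g. with and
#' without skull, or with different appendages) share their brain nodes.
#' This helper maps both mode sets to the DOFs of the common nodes (using
#' the `"node_origin"` attribute written by [strip_skull()]) and compares
#' there.
#'
#' @param A,B `modal_result` objects.
#' @param mesh_a,mesh_b the generating meshes.
#' @param threshold MAC pairing threshold.
#' @return a `mode_comparison` on the shared-node DOF basis.
#' @export
compare_on_common_nodes <- function(A, mesh_a, B, mesh_b, threshold = 0.5) {
  oa <- attr(mesh_a, "node_origin"); if (is.null(oa)) oa <- seq_len(nrow(mesh_a$nodes))
  ob <- attr(mesh_b, "node_origin"); if (is.null(ob)) ob <- seq_len(nrow(mesh_b$nodes))
  common <- intersect(oa, ob)
  if (length(common) == 0) stop("meshes share no nodes")
  ia <- match(common, oa); ib <- match(common, ob)
  dofs <- function(idx) as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  SA <- expand_to_full(A)[dofs(ia), , drop = FALSE]
  SB <- expand_to_full(B)[dofs(ib), , drop = FALSE]
  keep_a <- colSums(SA^2) > 0; keep_b <- colSums(SB^2) > 0
  cmp <- compare_modes(SA[, keep_a, drop = FALSE], SB[, keep_b, drop = FALSE],
                       threshold,
                       f_a = A$frequencies_hz[keep_a],
                       f_b = B$frequencies_hz[keep_b])
  cmp$mode_index_a <- which(keep_a)
  cmp$mode_index_b <- which(keep_b)
  cmp
}

#' @export
print.mode_comparison <- function(x, ...) {
  cat("<mode_comparison> ", nrow(x$mac), "x", ncol(x$mac),
      "modes, threshold", x$threshold, "\n")
  cat("  paired:", nrow(x$pairs),
      " unpaired A:", length(x$unpaired_a),
      " unpaired B:", length(x$unpaired_b), "\n")
  if (nrow(x$pairs)) {
    cat("  MAC range of pairs: [",
        sprintf("%.3f", min(x$pairs$mac)), ", ",
        sprintf("%.3f", max(x$pairs$mac)), "]\n", sep = "")
    if (!is.null(x$pairs$nrfd))
      cat("  NRFD range of pairs: [",
          sprintf("%.4f", min(x$pairs$nrfd)), ", ",
          sprintf("%.4f", max(x$pairs$nrfd)), "]\n", sep = "")
  }
  invisible(x)
}
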