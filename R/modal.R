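# Generalized eigenvalue extraction ([K] - omega^2 [M]) {phi} = 0 for the
# lowest modes, via shift-invert Lanczos in the M-inner product with full
# reorthogonalization, locking and restarts. The spectral transformation
# maps eigenvalues lambda = omega^2 to theta = 1/(lambda - sigma), so the
# modes nearest the shift become the dominant, fast-converging ones.

#' Solve for the lowest vibration modes
#'
#' Computes the `n_modes` algebraically smallest eigenvalues
#' `omega^2 >= 0` and mode shapes of `K phi = omega^2 M phi` on the free
#' DOFs of an assembled system. Constrained systems use shift
#' `sigma = 0` (K positive definite after fixing >= 3 non-collinear
#' nodes); unconstrained (free-free) systems use `sigma = -10` s^-2 so the
#' semidefinite `K` poses no factorization problem and the six rigid-body
#' modes are recovered as (numerically) zero frequencies.
#'
#' @param system an [assemble()]d, usually [apply_dirichlet()]-reduced,
#'   system with `n_free > n_modes`.
#' @param n_modes number of modes to extract (default 25).
#' @param sigma spectral shift in s^-2; default as described above.
#' @param tol relative residual tolerance: each accepted mode satisfies
#'   `||K phi - omega^2 M phi|| <= tol * ||K phi||` (rigid-body modes are
#'   checked against `||M phi||` scaled by the first elastic eigenvalue).
#' @param seed seed for the random Lanczos start vectors; fixed default
#'   makes results deterministic (up to eigenvector sign, which
#'   [normalize_modes()] then pins down).
#' @param max_restarts maximum number of restart cycles.
#'
#' @return an object of class `modal_result`: `frequencies_hz` (ascending),
#'   `omegas` (= 2 pi f, rad/s), `shapes` (n_free x n_modes, columns
#'   normalized to max entry +1), `residuals`, `free_dofs`, `n_nodes`,
#'   `n_requested`, `n_converged`, `normalization`.
#' @export
solve_modes <- function(system, n_modes = 25, sigma = NULL, tol = 1e-6,
                        seed = 1234L, max_restarts = 40L) {
  stopifnot(inherits(system, "assembled_system"))
  n <- system$n_free
  if (n <= 0) stop("system has no free DOFs")
  if (n_modes >= n) stop("n_modes must be < n_free (", n, ")")
  if (is.null(sigma)) sigma <- if (system$constrained) 0 else -10

  K <- system$K
  M <- system$M
  fac <- NULL
  for (shift in c(sigma, sigma - abs(sigma) * 1e-4 - 1e-4)) {
    fac <- tryCatch(
      Matrix::Cholesky(Matrix::forceSymmetric(K - shift * M),
                       LDL = FALSE, perm = TRUE),
      error = function(e) NULL)
    if (!is.null(fac)) { sigma <- shift; break }
  }
  if (is.null(fac))
    stop("factorization of K - sigma*M failed (shifted operator singular); ",
         "try a different sigma")

  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)

  Mx <- function(x) as.numeric(M %*% x)
  op <- function(x) as.numeric(Matrix::solve(fac, M %*% x, system = "A"))
  Mdot <- function(x, y) sum(x * Mx(y))

  m_kry <- min(n, max(2L * n_modes + 20L, 30L))
  locked_X <- matrix(0, n, 0)       # M-orthonormal converged vectors
  locked_lam <- numeric(0)

  # eigenvalue scale of the pencil, so (near-)zero rigid-body modes are
  # judged against ||M phi|| on a spectral scale rather than ||K phi|| ~ 0
  lam_scale <- sum(abs(Matrix::diag(K))) / sum(abs(Matrix::diag(M)))

  for (cycle in seq_len(max_restarts)) {
    if (ncol(locked_X) >= n_modes || ncol(locked_X) >= n) break

    # random start, M-orthogonal to locked vectors
    v <- stats::rnorm(n)
    if (ncol(locked_X)) v <- v - locked_X %*% crossprod(locked_X, Mx(v))
    nv <- sqrt(Mdot(v, v))
    if (nv < 1e-300) next
    v <- v / nv

    Vk <- matrix(0, n, m_kry)
    alpha <- numeric(m_kry); beta <- numeric(m_kry)
    Vk[, 1] <- v
    v_prev <- numeric(n)
    b_prev <- 0
    j_last <- m_kry
    for (j in seq_len(m_kry)) {
      w <- op(Vk[, j])
      if (ncol(locked_X)) w <- w - locked_X %*% crossprod(locked_X, Mx(w))
      alpha[j] <- Mdot(Vk[, j], w)
      w <- w - alpha[j] * Vk[, j] - b_prev * v_prev
      # full reorthogonalization (twice is enough)
      for (rep in 1:2)
        w <- w - Vk[, 1:j, drop = FALSE] %*%
          crossprod(Vk[, 1:j, drop = FALSE], Mx(w))
      bj <- sqrt(max(Mdot(w, w), 0))
      beta[j] <- bj
      if (bj < 1e-13 * max(abs(alpha[1:j]))) { j_last <- j; break }
      if (j < m_kry) {
        Vk[, j + 1] <- w / bj
        v_prev <- Vk[, j]
        b_prev <- bj
      }
      j_last <- j
    }

    Tj <- diag(alpha[1:j_last], j_last)
    if (j_last > 1) {
      off <- beta[1:(j_last - 1)]
      Tj[cbind(1:(j_last - 1), 2:j_last)] <- off
      Tj[cbind(2:j_last, 1:(j_last - 1))] <- off
    }
    et <- eigen(Tj, symmetric = TRUE)        # theta descending
    theta <- et$values
    good <- theta > 0 | sigma < 0            # keep lambda >= sigma side
    need <- n_modes - ncol(locked_X)

    accepted <- 0L
    for (idx in seq_along(theta)) {
      if (accepted >= need) break
      th <- theta[idx]
      if (th <= 0) next
      y <- et$vectors[, idx]
      x <- Vk[, 1:j_last, drop = FALSE] %*% y
      nx <- sqrt(Mdot(x, x))
      if (nx < 1e-300) next
      x <- x / nx
      lam <- sigma + 1 / th
      # direct residual check on the original pencil
      kx <- as.numeric(K %*% x)
      mx <- as.numeric(M %*% x)
      res <- sqrt(sum((kx - lam * mx)^2))
      ref <- max(sqrt(sum(kx^2)), lam_scale * sqrt(sum(mx^2)))
      if (res <= tol * ref) {
        locked_X <- cbind(locked_X, x)
        locked_lam <- c(locked_lam, lam)
        accepted <- accepted + 1L
      } else break   # Ritz values converge from the extremes inward
    }
  }

  n_conv <- length(locked_lam)
  if (n_conv < n_modes)
    stop("Lanczos did not converge: ", n_conv, " of ", n_modes,
         " modes accepted after ", max_restarts, " restarts")

  ord <- order(locked_lam)[seq_len(n_modes)]
  lam <- pmax(locked_lam[ord], 0)
  shapes <- locked_X[, ord, drop = FALSE]
  omega <- sqrt(lam)

  res <- vapply(seq_len(n_modes), function(i) {
    kx <- as.numeric(K %*% shapes[, i]); mx <- as.numeric(M %*% shapes[, i])
    sqrt(sum((kx - lam[i] * mx)^2)) /
      max(sqrt(sum(kx^2)), lam_scale * sqrt(sum(mx^2)), 1e-300)
  }, numeric(1))

  out <- structure(
    list(frequencies_hz = omega / (2 * pi), omegas = omega, shapes = shapes,
         residuals = res, free_dofs = system$free_dofs,
         n_nodes = system$n_nodes, n_requested = n_modes,
         n_converged = n_conv, sigma = sigma, normalization = "none"),
    class = "modal_result")
  normalize_modes(out)
}

#' Dense full-spectrum reference solver
#'
#' Independent oracle for [solve_modes()] on small systems: reduces the
#' generalized problem with a dense Cholesky factor of `M`
#' (`M = U^T U`, `S = U^-T K U^-1`) and calls `eigen()` on the full
#' symmetric spectrum. Intended for meshes with a few hundred free DOFs.
#'
#' @param system an [assemble()]d (optionally reduced) system.
#' @param n_modes number of lowest modes to return.
#' @return a `modal_result`, normalized like [solve_modes()].
#' @export
solve_modes_dense <- function(system, n_modes = 25) {
  stopifnot(inherits(system, "assembled_system"))
  n <- system$n_free
  if (n_modes > n) stop("n_modes must be <= n_free")
  K <- as.matrix(system$K)
  M <- as.matrix(system$M)
  U <- chol(M)
  Ui <- backsolve(U, diag(n))
  S <- crossprod(Ui, K %*% Ui)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  ord <- seq(n, n - n_modes + 1L)          # eigen() sorts descending
  lam <- pmax(es$values[ord], 0)
  shapes <- Ui %*% es$vectors[, ord, drop = FALSE]
  omega <- sqrt(lam)
  res <- vapply(seq_len(n_modes), function(i) {
    kx <- K %*% shapes[, i]; mx <- M %*% shapes[, i]
    sqrt(sum((kx - lam[i] * mx)^2)) / max(sqrt(sum(kx^2)), 1e-300)
  }, numeric(1))
  out <- structure(
    list(frequencies_hz = omega / (2 * pi), omegas = omega, shapes = shapes,
         residuals = res, free_dofs = system$free_dofs,
         n_nodes = system$n_nodes, n_requested = n_modes,
         n_converged = n_modes, sigma = NA_real_, normalization = "none"),
    class = "modal_result")
  normalize_modes(out)
}

#' Displacement-normalize mode shapes
#'
#' Scales each shape so its largest-magnitude entry equals +1 (the sign is
#' fixed to be positive at that entry). Idempotent; MAC values are
#' invariant to this scaling.
#'
#' @param result a `modal_result`.
#' @return the result with `normalization = "max_unit"`.
#' @export
normalize_modes <- function(result) {
  stopifnot(inherits(result, "modal_result"))
  shapes <- result$shapes
  for (i in seq_len(ncol(shapes))) {
    k <- which.max(abs(shapes[, i]))
    piv <- shapes[k, i]
    if (piv == 0) stop("mode ", i, " is a zero vector")
    shapes[, i] <- shapes[, i] / piv
  }
  result$shapes <- shapes
  result$normalization <- "max_unit"
  result
}

#' Expand mode shapes to the full displacement field
#'
#' Re-inserts the constrained DOFs as exact zeros, giving one displacement
#' vector of length `3 * n_nodes` per mode (for export, projection and
#' cross-mesh comparison).
#'
#' @param result a `modal_result`.
#' @param system the generating `assembled_system` (checked for a matching
#'   DOF map).
#' @return numeric matrix, `3 * n_nodes` rows, one column per mode.
#' @export
expand_to_full <- function(result, system = NULL) {
  stopifnot(inherits(result, "modal_result"))
  if (!is.null(system)) {
    if (!identical(result$free_dofs, system$free_dofs) ||
        result$n_nodes != system$n_nodes)
      stop("modal result and system have mismatched DOF maps")
  }
  full <- matrix(0, 3 * result$n_nodes, ncol(result$shapes))
  full[result$free_dofs, ] <- result$shapes
  full
}

#' Frequency table of a modal result
#'
#' @param result a `modal_result`.
#' @return data.frame with mode index, frequency (Hz), angular frequency
#'   (rad/s) and relative residual.
#' @export
frequency_table <- function(result) {
  stopifnot(inherits(result, "modal_result"))
  data.frame(mode = seq_along(result$frequencies_hz),
             f_hz = result$frequencies_hz,
             omega = result$omegas,
             residual = result$residuals)
}

#' @export
print.modal_result <- function(x, ...) {
  cat("<modal_result> ", x$n_converged, "converged /", x$n_requested,
      "requested modes on", length(x$free_dofs), "free DOFs\n")
  f <- x$frequencies_hz
  show <- utils::head(f, 10)
  cat("  f (Hz):", paste(sprintf("%.4g", show), collapse = ", "),
      if (length(f) > 10) "..." else "", "\n")
  cat("  max residual:", format(max(x$residuals), digits = 3), "\n")
  invisible(x)
}
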