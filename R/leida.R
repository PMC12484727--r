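# LEiDA-style extraction of recurring phase-alignment modes from
# synthetic BOLD-like signals, and projection of FE eigenmodes onto
# gray-matter parcels for eigenmode-vs-functional-mode comparison.

#' Simulate narrowband BOLD-like signals with planted phase-locking states
#'
#' The timeline is segmented into dwell blocks; each block is assigned one
#' of `K_states` states. In state 1 all regions oscillate in phase (the
#' global mode); in state `k > 1` a designated region subset oscillates in
#' anti-phase (offset pi) to the remainder. A common narrowband carrier
#' (default 0.05 cycles/sample) plus additive Gaussian noise completes the
#' signal. The planted truth (state sequence and unit-norm per-state
#' phase-alignment patterns) is recorded for parameter-recovery tests.
#'
#' @param n_regions number of regions (>= 2).
#' @param n_timepoints number of samples.
#' @param K_states number of planted states (>= 2).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (signal amplitude is 1).
#' @param seed RNG seed; the output is bitwise-deterministic per seed.
#' @param sampling_interval seconds per sample (metadata only).
#' @param carrier_freq carrier frequency in cycles per sample.
#' @param dwell state dwell time in samples.
#' @param state_probs optional probability weights for the states per
#'   block (default uniform). E.g. `c(0.5, rep(0.5/(K-1), K-1))` makes the
#'   global state occupy ~50% of the timeline.
#'
#' @return an object of class `signal_set`: `signals` (n_regions x
#'   n_timepoints), `sampling_interval`, and `planted_truth` with `state`
#'   (per timepoint), `patterns` (K_states x n_regions, unit rows) and
#'   `phase_offsets`.
#' @export
simulate_bold <- function(n_regions, n_timepoints, K_states = 8,
                          noise_sd = 0.2, seed = 1L,
                          sampling_interval = 1, carrier_freq = 0.05,
                          dwell = 50, state_probs = NULL) {
  if (n_regions < 2) stop("n_regions must be >= 2")
  if (K_states < 2) stop("K_states must be >= 2")
  if (n_timepoints < 2 * dwell) stop("n_timepoints too short for the dwell")
  if (!is.null(state_probs) && length(state_probs) != K_states)
    stop("state_probs must have one weight per state")

  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)

  # Anti-phase subsets: rotating blocks strictly smaller than half the
  # regions. A subset of exactly n/2 would make a state indistinguishable
  # from its complement (the phase-alignment matrix is identical), so
  # block sizes cycle through n/2 - 1, n/2 - 2, n/2 - 3.
  offsets <- matrix(0, K_states, n_regions)
  half <- floor(n_regions / 2)
  for (k in seq_len(K_states)[-1]) {
    size <- max(1, half - 1 - ((k - 2) %% 3))
    start <- 1 + ((k - 2) * max(1, floor(n_regions / (K_states - 1)))) %% n_regions
    members <- ((start - 1 + seq_len(size) - 1) %% n_regions) + 1
    offsets[k, members] <- pi
  }
  if (anyDuplicated(offsets))
    stop("planted states are not distinct; reduce K_states or increase ",
         "n_regions")
  patterns <- cos(offsets)                     # +1 / -1 block pattern
  patterns <- patterns / sqrt(rowSums(patterns^2))

  n_blocks <- ceiling(n_timepoints / dwell)
  block_state <- sample.int(K_states, n_blocks, replace = TRUE,
                            prob = state_probs)
  state <- rep(block_state, each = dwell)[seq_len(n_timepoints)]

  t_idx <- seq_len(n_timepoints) - 1
  carrier <- 2 * pi * carrier_freq * t_idx
  signals <- matrix(0, n_regions, n_timepoints)
  for (i in seq_len(n_regions))
    signals[i, ] <- cos(carrier + offsets[cbind(state, i)][seq_len(n_timepoints)])
  if (noise_sd > 0)
    signals <- signals + matrix(stats::rnorm(length(signals), sd = noise_sd),
                                n_regions, n_timepoints)

  structure(list(signals = signals, sampling_interval = sampling_interval,
                 planted_truth = list(state = state, patterns = patterns,
                                      phase_offsets = offsets,
                                      carrier_freq = carrier_freq)),
            class = "signal_set")
}

# Analytic signal via the FFT construction: zero the negative frequencies,
# double the positive ones, keep DC and (for even n) Nyquist.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of each region's signal
#'
#' Demeans each region and takes the phase of its analytic signal
#' (FFT-based Hilbert construction); values lie in `(-pi, pi]`.
#'
#' @param signals a `signal_set` or an `n_regions x n_timepoints` matrix.
#' @return matrix of phases (radians), same shape as the input.
#' @export
instantaneous_phase <- function(signals) {
  x <- if (inherits(signals, "signal_set")) signals$signals else as.matrix(signals)
  if (any(!is.finite(x))) stop("signals contain non-finite values")
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ] - mean(x[i, ])
    if (stats::sd(xi) == 0)
      stop("region ", i, " has a constant (zero-variance) signal")
    out[i, ] <- Arg(analytic_signal(xi))
  }
  out
}

#' Leading eigenvector of the phase-alignment matrix at each timepoint
#'
#' At each timepoint builds `A_ij = cos(theta_i - theta_j)` and returns its
#' unit-norm leading eigenvector, sign-flipped so that the majority of
#' components are negative (the convention under which the global in-phase
#' state maps to an all-same-sign vector). `A` is invariant to a global
#' phase shift, and for two anti-phase blocks it is exactly rank one with
#' the signed block pattern as its leading eigenvector.
#'
#' @param phases `n_regions x n_timepoints` phase matrix (radians).
#' @return `n_timepoints x n_regions` matrix, one unit-norm leading
#'   eigenvector per row.
#' @export
leading_eigenvector_series <- function(phases) {
  phases <- as.matrix(phases)
  n <- nrow(phases); tt <- ncol(phases)
  out <- matrix(0, tt, n)
  for (t in seq_len(tt)) {
    # A = cos(ti - tj) = cos t cos t' + sin t sin t' (rank 2, PSD)
    ct <- cos(phases[, t]); st <- sin(phases[, t])
    A <- tcrossprod(ct) + tcrossprod(st)
    es <- eigen(A, symmetric = TRUE)
    v <- es$vectors[, 1]
    v <- v / sqrt(sum(v^2))
    n_neg <- sum(v < 0)
    if (n_neg < n - n_neg || (n_neg == n - n_neg && sum(v) > 0)) v <- -v
    out[t, ] <- v
  }
  out
}

#' Cluster leading eigenvectors into recurring empirical modes
#'
#' k-means (multiple seeded restarts) over the per-timepoint leading
#' eigenvectors; the K cluster centroids, unit-normalized, are the
#' empirical phase-alignment modes, with occupancies given by cluster
#' fractions.
#'
#' @param eigenvector_series `n_timepoints x n_regions` matrix from
#'   [leading_eigenvector_series()].
#' @param K number of clusters (default 8).
#' @param seed RNG seed; results are deterministic per seed.
#' @param n_restarts number of k-means restarts (default 20).
#' @return an object of class `empirical_mode_set`: `centroids`
#'   (K x n_regions, unit rows), `occupancy` (sums to 1), `K`,
#'   `assignment` (cluster id per timepoint).
#' @export
cluster_modes <- function(eigenvector_series, K = 8, seed = 1L,
                          n_restarts = 20) {
  X <- as.matrix(eigenvector_series)
  if (nrow(X) < 5 * K)
    stop("series length must be well above K (have ", nrow(X), " rows)")
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  km <- NULL
  for (attempt in 1:5) {
    km <- tryCatch(
      stats::kmeans(X, centers = K, nstart = n_restarts, iter.max = 100),
      error = function(e) NULL)
    if (!is.null(km)) break
  }
  if (is.null(km)) stop("k-means failed to produce ", K, " clusters")
  cen <- km$centers
  cen <- cen / sqrt(rowSums(cen^2))
  occ <- as.vector(table(factor(km$cluster, levels = seq_len(K)))) / nrow(X)
  structure(list(centroids = cen, occupancy = occ, K = as.integer(K),
                 assignment = km$cluster),
            class = "empirical_mode_set")
}

#' Project an FE mode shape onto gray-matter surface parcels
#'
#' Per parcel, the mean signed radial displacement of the parcel's
#' gray-matter surface nodes (radial direction taken from the mesh
#' centroid), z-scored across parcels. This quantifies the "high relative
#' displacement" maps used to relate resonance modes to regional activity
#' patterns.
#'
#' @param mode_field full displacement field (length `3 * n_nodes`) from
#'   [expand_to_full()], or a matrix with one mode per column.
#' @param mesh the [labeled_mesh()] carrying parcel labels.
#' @return numeric vector of length `n_parcels` (or a matrix, one row per
#'   parcel, for matrix input).
#' @export
project_mode_to_parcels <- function(mode_field, mesh) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  labeled <- which(!is.na(mesh$parcel))
  if (length(labeled) == 0) stop("mesh has no parcel labels")
  parcels <- sort(unique(mesh$parcel[labeled]))
  fld <- as.matrix(mode_field)
  if (nrow(fld) != 3 * nrow(mesh$nodes))
    stop("mode_field must have 3 * n_nodes entries (expand_to_full first)")
  centroid <- colMeans(mesh$nodes)
  rad <- sweep(mesh$nodes[labeled, , drop = FALSE], 2, centroid)
  rad <- rad / sqrt(rowSums(rad^2))
  dofs <- cbind(3 * labeled - 2, 3 * labeled - 1, 3 * labeled)
  out <- matrix(0, length(parcels), ncol(fld))
  for (m in seq_len(ncol(fld))) {
    u <- cbind(fld[dofs[, 1], m], fld[dofs[, 2], m], fld[dofs[, 3], m])
    radial <- rowSums(u * rad)
    means <- vapply(parcels, function(p) {
      sel <- mesh$parcel[labeled] == p
      if (!any(sel)) stop("parcel ", p, " has no nodes")
      mean(radial[sel])
    }, numeric(1))
    s <- stats::sd(means)
    out[, m] <- if (s == 0) rep(0, length(means)) else
      (means - mean(means)) / s
  }
  if (ncol(out) == 1) drop(out) else out
}

#' Match projected eigenmodes to empirical modes
#'
#' Absolute cosine similarity between parcel-projected eigenmode vectors
#' and empirical-mode centroids (sign-invariant, since eigenmode sign is
#' arbitrary), plus the optimal one-to-one best-match assignment.
#'
#' @param parcel_vectors matrix with one parcel-projected eigenmode per
#'   row (or a single vector).
#' @param modes an `empirical_mode_set` (or a plain centroid matrix, one
#'   mode per row).
#' @return list with `similarity` (|cosine| matrix, eigenmodes x empirical
#'   modes) and `best_match` data.frame (`eigenmode`, `empirical`,
#'   `similarity`).
#' @export
match_eigenmodes_to_empirical <- function(parcel_vectors, modes) {
  V <- if (is.matrix(parcel_vectors)) parcel_vectors else
    matrix(parcel_vectors, nrow = 1)
  C <- if (inherits(modes, "empirical_mode_set")) modes$centroids else
    as.matrix(modes)
  if (ncol(V) != ncol(C))
    stop("dimension mismatch: ", ncol(V), " parcels vs ", ncol(C),
         " empirical-mode regions")
  Vn <- V / sqrt(rowSums(V^2))
  Cn <- C / sqrt(rowSums(C^2))
  sim <- abs(tcrossprod(Vn, Cn))
  assign_ab <- solve_assignment(-sim)
  rows <- which(!is.na(assign_ab))
  best <- data.frame(eigenmode = rows, empirical = assign_ab[rows],
                     similarity = sim[cbind(rows, assign_ab[rows])])
  list(similarity = sim, best_match = best)
}

#' @export
print.empirical_mode_set <- function(x, ...) {
  cat("<empirical_mode_set> K =", x$K, "modes over", ncol(x$centroids),
      "regions\n")
  cat("  occupancy:", paste(sprintf("%.3f", x$occupancy), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.signal_set <- function(x, ...) {
  cat("<signal_set>", nrow(x$signals), "regions x", ncol(x$signals),
      "timepoints, dt =", x$sampling_interval, "s\n")
  if (!is.null(x$planted_truth))
    cat("  planted states:", nrow(x$planted_truth$patterns), "\n")
  invisible(x)
}
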