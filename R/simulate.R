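#' Simulate a multichannel series from a causal graph
#'
#' Draws `x_t = sum_k A_k x_{t-k} + e_t` with independent Gaussian
#' innovations `e_t ~ N(0, diag(noise_vars))`, discarding an initial burn-in
#' so the retained samples are (approximately) from the stationary
#' distribution.
#'
#' @param graph a stable [causal_graph()].
#' @param n_timepoints number of retained samples `T` (must exceed 10x the
#'   VAR order).
#' @param burn_in samples discarded before recording; default 500.
#' @param seed integer seed; the output is deterministic given it.
#' @param tr_seconds sampling interval attached to the output (seconds).
#' @return a `T x n_nodes` numeric matrix with column names from the graph
#'   and attribute `sampling_interval`.
#' @examples
#' g <- causal_graph(matrix(0.9, 1, 1))
#' x <- simulate_var(g, 1000, seed = 1)
#' var(x[, 1])  # near 1 / (1 - 0.81)
#' @export
simulate_var <- function(graph, n_timepoints, burn_in = 500L, seed = NULL,
                         tr_seconds = 2) {
  stopifnot(inherits(graph, "causal_graph"))
  p <- graph$order
  n <- graph$n_nodes
  if (n_timepoints <= 10L * p)
    stop("`n_timepoints` must exceed 10x the VAR order")
  rho <- spectral_radius(graph)
  if (rho >= 1)
    stop(sprintf("unstable causal graph: spectral radius %.4f >= 1", rho))
  if (!is.null(seed)) set.seed(seed)
  sds <- sqrt(graph$noise_vars)
  total <- n_timepoints + burn_in
  e <- matrix(stats::rnorm(total * n), total, n) %*% diag(sds, n)
  x <- matrix(0, total, n)
  a <- graph$coeffs
  for (t in seq_len(total)) {
    xt <- e[t, ]
    for (k in seq_len(min(p, t - 1L)))
      xt <- xt + a[[k]] %*% x[t - k, ]
    x[t, ] <- xt
  }
  out <- x[burn_in + seq_len(n_timepoints), , drop = FALSE]
  colnames(out) <- graph$node_names
  attr(out, "sampling_interval") <- tr_seconds
  out
}

#' Canonical double-gamma hemodynamic response kernel
#'
#' SPM-style canonical HRF (peak at 6 s, undershoot at 16 s, undershoot
#' ratio 1/6) sampled at the acquisition interval and truncated at 32 s.
#'
#' @param tr_seconds sampling interval in seconds.
#' @param duration kernel length in seconds.
#' @return numeric vector of kernel weights, normalized to unit sum.
#' @export
hrf_kernel <- function(tr_seconds, duration = 32) {
  stopifnot(tr_seconds > 0)
  t <- seq(0, duration, by = tr_seconds)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / sum(h)
}

#' Convolve channels with the canonical HRF
#'
#' Makes simulated neural series BOLD-like by convolving each channel with
#' the canonical double-gamma hemodynamic response sampled at the series'
#' repetition time. The output has the same length as the input (causal
#' convolution, tail truncated).
#'
#' @param ts `T x N` series matrix.
#' @param tr_seconds sampling interval in seconds; defaults to the matrix's
#'   `sampling_interval` attribute.
#' @return matrix of the same shape, attributes preserved.
#' @export
convolve_hrf <- function(ts, tr_seconds = attr(ts, "sampling_interval")) {
  if (is.null(tr_seconds)) tr_seconds <- 2
  stopifnot(is.matrix(ts), tr_seconds > 0)
  h <- hrf_kernel(tr_seconds)
  out <- apply(ts, 2L, function(x)
    stats::convolve(x, rev(h), type = "open")[seq_along(x)])
  dimnames(out) <- dimnames(ts)
  attr(out, "sampling_interval") <- tr_seconds
  out
}

#' Gaussian blob spatial maps on a small voxel grid
#'
#' One peak-normalized 3D Gaussian blob per node, with centres spread over
#' the grid. Used to paint network time courses into synthetic voxel images.
#'
#' @param n_nodes number of maps.
#' @param dims grid dimensions, default `c(12, 14, 12)`.
#' @param radius Gaussian sd of each blob in voxels.
#' @return `n_nodes x prod(dims)` matrix with attribute `dims`; each row is
#'   in `[0, 1]` with maximum 1.
#' @export
blob_maps <- function(n_nodes, dims = c(12L, 14L, 12L), radius = 1.6) {
  stopifnot(n_nodes >= 1L, length(dims) == 3L)
  # centres: lattice positions spread through the volume
  grid <- as.matrix(expand.grid(x = seq_len(dims[1L]), y = seq_len(dims[2L]),
                                z = seq_len(dims[3L])))
  centres <- cbind(
    x = dims[1L] * (0.25 + 0.5 * ((seq_len(n_nodes) - 1L) %% 2L)),
    y = dims[2L] * (0.2 + 0.6 * ((seq_len(n_nodes) - 1L) %/% 2L) /
                      max(1, ceiling(n_nodes / 2) - 1)),
    z = dims[3L] * (0.3 + 0.4 * ((seq_len(n_nodes) - 1L) %% 3L) / 2))
  maps <- matrix(0, n_nodes, nrow(grid))
  for (i in seq_len(n_nodes)) {
    d2 <- rowSums(sweep(grid, 2L, centres[i, ])^2)
    m <- exp(-d2 / (2 * radius^2))
    maps[i, ] <- m / max(m)
  }
  attr(maps, "dims") <- as.integer(dims)
  maps
}

#' Render node time courses into a synthetic 4D voxel image
#'
#' Each voxel's series is the map-weighted sum of the node series plus
#' white Gaussian noise: `v(t) = sum_i map_i(v) x_i(t) + noise`. This is
#' the planted-ground-truth input for the group ICA stage.
#'
#' @param maps `n_nodes x n_voxels` non-negative, peak-normalized spatial
#'   maps with attribute `dims` (from [blob_maps()]).
#' @param ts `T x n_nodes` node series matrix.
#' @param noise_sd sd of the additive voxel noise.
#' @param seed optional integer seed for the noise.
#' @return a `voxel_image`: `T x n_voxels` matrix with attributes `dims` and
#'   `sampling_interval`.
#' @export
render_voxels <- function(maps, ts, noise_sd = 0.1, seed = NULL) {
  stopifnot(is.matrix(maps), is.matrix(ts))
  if (nrow(maps) != ncol(ts))
    stop(sprintf("map/channel mismatch: %d maps for %d channels",
                 nrow(maps), ncol(ts)))
  if (any(maps < 0)) stop("maps must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  img <- ts %*% maps
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), sd = noise_sd), nrow(img))
  attr(img, "dims") <- attr(maps, "dims")
  attr(img, "sampling_interval") <- attr(ts, "sampling_interval")
  class(img) <- c("voxel_image", class(img))
  img
}
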