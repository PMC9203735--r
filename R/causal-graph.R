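#' Directed VAR causal graph
#'
#' A `causal_graph` holds the coefficient structure of a stable vector
#' autoregressive (VAR) process: `p` lag matrices of size `n x n` whose entry
#' `coeffs[[k]][i, j]` is the influence of node `j` at lag `k` on node `i`,
#' together with per-node innovation variances. It is the ground truth of the
#' synthetic studies and the generative twin of the MVAR model fitted by
#' [mvar()].
#'
#' @param coeffs a single `n x n` matrix (VAR(1)) or a list of `p` such
#'   matrices, lag 1 first. Entry `[i, j]` is the effect of node `j` on node
#'   `i` (source = column, target = row).
#' @param noise_vars per-node innovation variances, recycled to `n`.
#'   All must be strictly positive.
#' @param node_names optional character labels for the nodes; defaults to
#'   column names of the first lag matrix, then `"X1"`, `"X2"`, ...
#' @return an object of class `causal_graph` with fields `n_nodes`, `order`,
#'   `coeffs` (list of lag matrices), `noise_vars`, `node_names`.
#' @examples
#' g <- causal_graph(matrix(c(0.5, 0.4, 0, 0.5), 2, 2), noise_vars = 1)
#' spectral_radius(g)
#' @export
causal_graph <- function(coeffs, noise_vars = 1, node_names = NULL) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  if (!is.list(coeffs) || length(coeffs) < 1L)
    stop("`coeffs` must be a matrix or a non-empty list of matrices")
  n <- nrow(coeffs[[1L]])
  for (a in coeffs) {
    if (!is.matrix(a) || nrow(a) != n || ncol(a) != n)
      stop("all lag matrices must be square with matching dimension")
    if (!all(is.finite(a))) stop("coefficients must be finite")
  }
  noise_vars <- rep_len(as.numeric(noise_vars), n)
  if (any(!is.finite(noise_vars)) || any(noise_vars <= 0))
    stop("`noise_vars` must be strictly positive and finite")
  if (is.null(node_names)) node_names <- colnames(coeffs[[1L]])
  if (is.null(node_names)) node_names <- paste0("X", seq_len(n))
  coeffs <- lapply(coeffs, function(a) {
    dimnames(a) <- list(node_names, node_names)
    a
  })
  structure(
    list(n_nodes = n, order = length(coeffs), coeffs = coeffs,
         noise_vars = noise_vars, node_names = node_names),
    class = "causal_graph")
}

#' Spectral radius of the VAR companion matrix
#'
#' The process is (second-order) stationary iff the spectral radius is
#' strictly below one.
#'
#' @param graph a [causal_graph()] or an object with `coeffs` (list of lag
#'   matrices).
#' @return largest eigenvalue modulus of the companion matrix.
#' @export
spectral_radius <- function(graph) {
  a <- graph$coeffs
  n <- nrow(a[[1L]])
  p <- length(a)
  comp <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) comp[seq_len(n), (k - 1L) * n + seq_len(n)] <- a[[k]]
  if (p > 1L)
    comp[n + seq_len(n * (p - 1L)), seq_len(n * (p - 1L))] <-
      diag(n * (p - 1L))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

is_stable <- function(graph, tol = 1e-8) spectral_radius(graph) < 1 - tol

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("Causal graph: %d nodes, VAR order %d, spectral radius %.3f\n",
              x$n_nodes, x$order, spectral_radius(x)))
  cat("Nodes:", paste(x$node_names, collapse = ", "), "\n")
  nz <- 0L
  for (k in seq_along(x$coeffs)) {
    idx <- which(x$coeffs[[k]] != 0, arr.ind = TRUE)
    nz <- nz + nrow(idx)
  }
  cat(sprintf("Non-zero coefficients: %d (source = column, target = row)\n",
              nz))
  invisible(x)
}

#' Default six-network causal graph
#'
#' A stable VAR(1) over the six canonical resting-state networks (ECN, VN,
#' SMN, RFPN, DMN, SN) used as the base ground truth of synthetic studies.
#' Every node has moderate autoregression; a handful of directed
#' inter-network edges carry the causal structure, among them the
#' sensorimotor-to-default-mode edge (`SMN -> DMN`) that the synthetic
#' group/session manipulations act on.
#'
#' @param edge_strength coefficient of the SMN -> DMN edge.
#' @return a [causal_graph()].
#' @export
default_study_graph <- function(edge_strength = 0.4) {
  nets <- c("ECN", "VN", "SMN", "RFPN", "DMN", "SN")
  a <- diag(0.3, 6)
  dimnames(a) <- list(nets, nets)
  a["DMN", "SMN"] <- edge_strength   # the manipulated edge
  a["SN", "ECN"] <- 0.25
  a["VN", "RFPN"] <- 0.2
  a["ECN", "DMN"] <- -0.2
  causal_graph(a, noise_vars = 1, node_names = nets)
}
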