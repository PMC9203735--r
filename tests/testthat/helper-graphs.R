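# shared fixtures: random stable graphs and an independent GPDC oracle

# random stable VAR graph: coefficients drawn N(0, 0.3) and rescaled until
# the companion spectral radius is <= target
random_stable_graph <- function(n, p, seed, target_radius = 0.85) {
  set.seed(seed)
  coeffs <- lapply(seq_len(p), function(k)
    matrix(rnorm(n * n, sd = 0.3), n, n))
  g <- causal_graph(coeffs, noise_vars = runif(n, 0.5, 2))
  while (spectral_radius(g) > target_radius) {
    coeffs <- lapply(coeffs, function(a) a * 0.8)
    g <- causal_graph(coeffs, g$noise_vars)
  }
  g
}

# brute-force GPDC oracle: literal summation of the polynomial terms and
# elementwise evaluation of the definition, independent of transfer_matrix()
gpdc_oracle <- function(coeffs, noise_vars, f_norm) {
  n <- nrow(coeffs[[1]])
  ab <- matrix(0 + 0i, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      s <- if (i == j) 1 + 0i else 0 + 0i
      for (k in seq_along(coeffs))
        s <- s - coeffs[[k]][i, j] *
          (cos(2 * pi * f_norm * k) - 1i * sin(2 * pi * f_norm * k))
      ab[i, j] <- s
    }
  out <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      denom <- 0
      for (k in seq_len(n))
        denom <- denom + Mod(ab[k, j])^2 / noise_vars[k]
      out[i, j] <- (Mod(ab[i, j]) / sqrt(noise_vars[i])) / sqrt(denom)
    }
  out
}

# mvar-shaped object straight from a causal graph (no estimation)
graph_as_model <- function(graph, tr = 2) {
  structure(list(order = graph$order, coeffs = graph$coeffs,
                 noise_vars = graph$noise_vars,
                 channel_names = graph$node_names,
                 sampling_interval = tr),
            class = "mvar")
}

# pull one directed edge row out of an edge_test_result
edge_row <- function(result, source, target) {
  result[result$source == source & result$target == target, ]
}
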