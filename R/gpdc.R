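#' Spectral transfer polynomial of an MVAR model
#'
#' Evaluates `A_bar(f) = I - sum_{k=1..p} A_k exp(-i 2 pi f k)` at a
#' normalized frequency `f` (cycles per sample). This Fourier-domain
#' coefficient matrix is the building block of partial directed coherence
#' measures.
#'
#' @param model an [mvar()] fit (or any object with `coeffs`).
#' @param f_norm normalized frequency in `[0, 0.5]`.
#' @return complex `N x N` matrix.
#' @export
transfer_matrix <- function(model, f_norm) {
  stopifnot(f_norm >= 0, f_norm <= 0.5)
  a <- model$coeffs
  n <- nrow(a[[1L]])
  ab <- diag(n) + 0i
  for (k in seq_along(a))
    ab <- ab - a[[k]] * exp(-2i * pi * f_norm * k)
  ab
}

#' Generalized partial directed coherence spectrum
#'
#' Computes `|pi_ij(f)| = (|A_bar_ij(f)| / sigma_i) /
#' sqrt(sum_k |A_bar_kj(f)|^2 / sigma_k^2)` on a grid of physical
#' frequencies, where `sigma_i^2` are the fitted innovation variances. GPDC
#' measures the directed influence of channel `j` (source, column) on
#' channel `i` (target, row) at frequency `f`; for every source and
#' frequency the squared values sum to one over targets (self-terms
#' included).
#'
#' @param model an [mvar()] fit.
#' @param freqs_hz frequency grid in Hz; default 129 evenly spaced points on
#'   `[0, Nyquist]`.
#' @param sampling_interval seconds per sample; defaults to the model's.
#' @param n_freqs grid size when `freqs_hz` is not given.
#' @return an object of class `gpdc_spectrum`: `freqs` (Hz), `values`
#'   (`N x N x F` array of `|pi_ij(f)|`), `channel_names`,
#'   `sampling_interval`.
#' @examples
#' a <- matrix(c(0, 0.5, 0, 0), 2, 2)  # X1 -> X2
#' m <- list(order = 1, coeffs = list(a), noise_vars = c(1, 1),
#'           channel_names = c("X1", "X2"), sampling_interval = 2)
#' class(m) <- "mvar"
#' sp <- gpdc(m)
#' sp$values[2, 1, 1]  # 0.5 / sqrt(1.25)
#' @export
gpdc <- function(model, freqs_hz = NULL,
                 sampling_interval = model$sampling_interval,
                 n_freqs = 129L) {
  if (is.null(sampling_interval)) sampling_interval <- 2
  if (any(model$noise_vars <= 0))
    stop("degenerate residuals: non-positive innovation variance")
  nyq <- 1 / (2 * sampling_interval)
  if (is.null(freqs_hz)) freqs_hz <- seq(0, nyq, length.out = n_freqs)
  if (any(freqs_hz > nyq + 1e-12))
    stop(sprintf("frequencies above Nyquist (%.4f Hz)", nyq))
  n <- length(model$noise_vars)
  inv_sd <- 1 / sqrt(model$noise_vars)
  vals <- array(NA_real_, c(n, n, length(freqs_hz)))
  for (fi in seq_along(freqs_hz)) {
    ab <- transfer_matrix(model, freqs_hz[fi] * sampling_interval)
    w <- Mod(ab) * inv_sd          # |A_bar_ij| / sigma_i, row-wise weight
    vals[, , fi] <- sweep(w, 2L, sqrt(colSums(w^2)), "/")
  }
  nm <- model$channel_names %||% paste0("X", seq_len(n))
  dimnames(vals) <- list(target = nm, source = nm, NULL)
  structure(list(freqs = freqs_hz, values = vals, channel_names = nm,
                 sampling_interval = sampling_interval),
            class = "gpdc_spectrum")
}

#' @export
print.gpdc_spectrum <- function(x, ...) {
  cat(sprintf(
    "GPDC spectrum: %d channels, %d frequencies on [%.3g, %.3g] Hz\n",
    length(x$channel_names), length(x$freqs), min(x$freqs), max(x$freqs)))
  cat("values[i, j, f] = influence of source j on target i at frequency f\n")
  invisible(x)
}

#' @describeIn gpdc plot the off-diagonal GPDC spectra, one panel per
#'   source channel.
#' @param x a `gpdc_spectrum`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gpdc_spectrum <- function(x, ...) {
  n <- length(x$channel_names)
  old <- graphics::par(mfrow = c(1, n), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (j in seq_len(n)) {
    y <- t(x$values[-j, j, , drop = TRUE])
    if (is.null(dim(y))) y <- matrix(y, ncol = 1L)
    graphics::matplot(x$freqs, y, type = "l", lty = 1, ylim = c(0, 1),
                      xlab = "frequency (Hz)", ylab = "|GPDC|",
                      main = paste("source", x$channel_names[j]), ...)
  }
  invisible(x)
}

#' Band-averaged GPDC edge matrix
#'
#' Entrywise mean of `|pi_ij(f)|` over grid frequencies falling in
#' `[low_hz, high_hz]` (inclusive). The default band, 0.01-0.1 Hz, is the
#' resting-state BOLD band; the result is the directed
#' effective-connectivity edge matrix used for group inference.
#'
#' @param spec a [gpdc()] spectrum.
#' @param low_hz,high_hz band edges in Hz.
#' @return `N x N` matrix of band-averaged GPDC (source = column,
#'   target = row), entries in `[0, 1]`.
#' @export
band_average <- function(spec, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(spec, "gpdc_spectrum"))
  sel <- spec$freqs >= low_hz & spec$freqs <= high_hz
  if (sum(sel) < 2L)
    stop(sprintf(
      "band [%g, %g] Hz intersects the frequency grid in %d point(s); >= 2 required",
      low_hz, high_hz, sum(sel)))
  out <- apply(spec$values[, , sel, drop = FALSE], c(1L, 2L), mean)
  dimnames(out) <- list(spec$channel_names, spec$channel_names)
  out
}

#' Band-averaged GPDC edge matrix from raw series
#'
#' Convenience wrapper: AIC order selection (unless `order` is given), MVAR
#' fit, GPDC spectrum, band average.
#'
#' @param ts `T x N` series matrix.
#' @param order VAR order; if `NULL`, chosen by [select_order_aic()].
#' @param p_max maximal candidate order for AIC.
#' @param band frequency band in Hz.
#' @param n_freqs frequency-grid size.
#' @return `N x N` edge matrix with attribute `order` (the order used).
#' @export
edge_matrix <- function(ts, order = NULL, p_max = 6L, band = c(0.01, 0.1),
                        n_freqs = 129L) {
  if (is.null(order)) order <- as.integer(select_order_aic(ts, p_max))
  fit <- mvar(ts, order)
  structure(band_average(gpdc(fit, n_freqs = n_freqs), band[1L], band[2L]),
            order = order)
}

# phase-randomized surrogate of one channel: amplitude spectrum preserved,
# phases drawn uniformly with Hermitian symmetry
phase_randomize <- function(x) {
  t_n <- length(x)
  f <- stats::fft(x)
  half <- floor((t_n - 1) / 2)
  if (half >= 1L) {
    ph <- stats::runif(half, 0, 2 * pi)
    f[2L:(half + 1L)] <- Mod(f[2L:(half + 1L)]) * exp(1i * ph)
    f[t_n:(t_n - half + 1L)] <- Conj(f[2L:(half + 1L)])
  }
  Re(stats::fft(f, inverse = TRUE)) / t_n
}

#' Surrogate-based edge detection
#'
#' Tests each directed edge's band-averaged GPDC against a null in which
#' all cross-channel dependence is destroyed: every channel is
#' independently phase-randomized (amplitude spectra preserved), the edge
#' matrix is recomputed per surrogate, and an edge is detected when the
#' rank-based surrogate p-value `(1 + #{surrogate >= observed}) /
#' (1 + n_surrogates)` falls at or below `alpha`.
#'
#' @param ts `T x N` series matrix.
#' @param n_surrogates number of surrogates; must satisfy
#'   `(1 + n_surrogates) * alpha >= 1`.
#' @param alpha per-edge level.
#' @param seed integer seed.
#' @param order VAR order for all fits; if `NULL`, AIC-selected on the
#'   observed series and reused for surrogates.
#' @param band frequency band in Hz.
#' @return list with `detected` (logical `N x N`, diagonal `NA`),
#'   `observed` (edge matrix), `pvals` (`N x N`), `order`.
#' @export
detect_edges_surrogate <- function(ts, n_surrogates = 99L, alpha = 0.05,
                                   seed = NULL, order = NULL,
                                   band = c(0.01, 0.1)) {
  if ((1 + n_surrogates) * alpha < 1)
    stop(sprintf(
      "%d surrogates cannot resolve alpha = %g; need at least %d",
      n_surrogates, alpha, ceiling(1 / alpha) - 1L))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(order)) order <- as.integer(select_order_aic(ts))
  obs <- edge_matrix(ts, order = order, band = band)
  n <- ncol(ts)
  exceed <- matrix(0L, n, n)
  for (s in seq_len(n_surrogates)) {
    sur <- apply(ts, 2L, phase_randomize)
    attr(sur, "sampling_interval") <- attr(ts, "sampling_interval")
    es <- edge_matrix(sur, order = order, band = band)
    exceed <- exceed + (es >= obs)
  }
  pvals <- (1 + exceed) / (1 + n_surrogates)
  detected <- pvals <= alpha
  diag(detected) <- NA
  dimnames(pvals) <- dimnames(detected) <- dimnames(obs)
  list(detected = detected, observed = obs, pvals = pvals, order = order)
}
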