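#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (zero phase) to each channel, after per-channel demeaning. The default
#' band, 0.01-0.1 Hz, is the canonical low-frequency window of resting-state
#' BOLD fluctuations.
#'
#' @param ts `T x N` series matrix with attribute `sampling_interval`
#'   (seconds), or supply `tr_seconds`.
#' @param low_hz,high_hz band edges in Hz.
#' @param tr_seconds sampling interval override.
#' @return filtered matrix, same shape, zero mean per channel.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.1,
                     tr_seconds = attr(ts, "sampling_interval")) {
  stopifnot(is.matrix(ts))
  if (is.null(tr_seconds)) stop("sampling interval unknown; pass `tr_seconds`")
  nyq <- 1 / (2 * tr_seconds)
  if (high_hz >= nyq)
    stop(sprintf(
      "band edge %.3f Hz is not below the Nyquist frequency %.3f Hz",
      high_hz, nyq))
  if (low_hz <= 0 || low_hz >= high_hz)
    stop("need 0 < low_hz < high_hz")
  bf <- signal::butter(4, c(low_hz, high_hz) / nyq, type = "pass")
  out <- apply(ts, 2L, function(x) {
    y <- iir_filtfilt(bf$b, bf$a, x - mean(x))
    y - mean(y)
  })
  dimnames(out) <- dimnames(ts)
  attr(out, "sampling_interval") <- tr_seconds
  out
}

#' CompCor-style noise components
#'
#' Principal-component time courses of the variance-normalized
#' noise-compartment voxel series, for use as nuisance regressors.
#'
#' @param noise_series `T x V` matrix of noise-compartment voxel series.
#' @param k number of components; `k = 0` returns a 0-column matrix.
#' @return `T x k` matrix of unit-variance, mutually orthogonal components.
#' @export
compcor_components <- function(noise_series, k = 5L) {
  stopifnot(is.matrix(noise_series), k >= 0L)
  t_n <- nrow(noise_series)
  if (k == 0L) return(matrix(0, t_n, 0L))
  if (k >= min(dim(noise_series)))
    stop("`k` must be below both the frame count and the voxel count")
  sds <- apply(noise_series, 2L, stats::sd)
  if (all(sds == 0)) stop("noise series are constant; no components exist")
  z <- scale(noise_series[, sds > 0, drop = FALSE])
  pcs <- stats::prcomp(z, center = FALSE, scale. = FALSE)$x[, seq_len(k),
                                                            drop = FALSE]
  scale(pcs, center = TRUE, scale = apply(pcs, 2L, stats::sd))
}

#' Regress confounds out of every channel
#'
#' Least-squares residuals of each channel on an intercept plus the given
#' regressors. Collinear regressor columns are dropped with a warning.
#'
#' @param ts `T x N` series matrix.
#' @param regressors `T x q` matrix (possibly 0 columns).
#' @return residual matrix, same shape as `ts`; with no regressors this is
#'   the demeaned input.
#' @export
regress_confounds <- function(ts, regressors) {
  stopifnot(is.matrix(ts))
  if (is.null(regressors) || NCOL(regressors) == 0L)
    return(structure(scale(ts, scale = FALSE)[, , drop = FALSE],
                     sampling_interval = attr(ts, "sampling_interval"),
                     dimnames = dimnames(ts)))
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != nrow(ts))
    stop("regressors must have one row per frame")
  x <- cbind(1, regressors)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    warning(sprintf("dropping %d collinear regressor column(s)",
                    ncol(x) - qx$rank))
    x <- x[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(x)
  }
  out <- qr.resid(qx, ts)
  dimnames(out) <- dimnames(ts)
  attr(out, "sampling_interval") <- attr(ts, "sampling_interval")
  out
}

#' Flag motion-outlier frames
#'
#' A frame is censored iff its framewise displacement strictly exceeds
#' `fd_thresh` (mm) or its standardized DVARS strictly exceeds
#' `dvars_thresh`. The defaults are the standard fMRIPrep-style thresholds
#' of 0.5 mm and 1.5.
#'
#' @param conf a confound table (data.frame or matrix) with columns
#'   `framewise_displacement` and `std_dvars`.
#' @param fd_thresh,dvars_thresh censoring thresholds.
#' @return a `censor_mask`: list with `keep` (logical, TRUE = retained) and
#'   `reason` (character per frame: `""`, `"FD"`, `"DVARS"` or
#'   `"FD+DVARS"`).
#' @export
censor_outliers <- function(conf, fd_thresh = 0.5, dvars_thresh = 1.5) {
  stopifnot(fd_thresh > 0, dvars_thresh > 0)
  fd <- conf[["framewise_displacement"]]
  dv <- conf[["std_dvars"]]
  if (is.null(fd) || is.null(dv))
    stop("confound table needs `framewise_displacement` and `std_dvars`")
  bad_fd <- fd > fd_thresh
  bad_dv <- dv > dvars_thresh
  reason <- rep("", length(fd))
  reason[bad_fd & !bad_dv] <- "FD"
  reason[!bad_fd & bad_dv] <- "DVARS"
  reason[bad_fd & bad_dv] <- "FD+DVARS"
  structure(list(keep = !(bad_fd | bad_dv), reason = reason),
            class = "censor_mask")
}

#' @export
print.censor_mask <- function(x, ...) {
  cat(sprintf("Censor mask: %d of %d frames flagged\n",
              sum(!x$keep), length(x$keep)))
  if (any(!x$keep)) print(table(x$reason[!x$keep]))
  invisible(x)
}

# one IIR pass, steady-state initialized as if the input had been held at
# x0 forever (so the output starts at the DC-gain level, with no step
# transient); FIR part via convolution, AR part via the C-level recursion
iir_filter <- function(b, a, x, x0) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b))) / a[1L]
  a <- c(a, numeric(n - length(a))) / a[1L]
  v <- stats::filter(c(rep(x0, n - 1L), x), b, sides = 1L)
  v <- v[n - 1L + seq_along(x)]
  k_dc <- sum(b) / sum(a)
  as.numeric(stats::filter(v, -a[-1L], method = "recursive",
                           init = rep(k_dc * x0, n - 1L)))
}

# zero-phase forward-backward IIR filtering with odd-reflection padding and
# steady-state initial conditions (the standard transient-free realization)
iir_filtfilt <- function(b, a, x, pad = length(x) - 1L) {
  pad <- min(length(x) - 1L, pad)
  ext <- c(2 * x[1L] - x[1L + pad:1], x,
           2 * x[length(x)] - x[length(x) - 1:pad])
  y <- iir_filter(b, a, ext, ext[1L])
  y <- rev(iir_filter(b, a, rev(y), y[length(y)]))
  y[pad + seq_along(x)]
}

# longest contiguous run of TRUE in a logical vector -> index range
longest_keep_run <- function(keep) {
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  ok <- which(r$values)
  if (length(ok) == 0L) return(integer(0))
  best <- ok[which.max(r$lengths[ok])]
  (ends[best] - r$lengths[best] + 1L):ends[best]
}
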