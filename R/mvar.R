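#' Fit a multivariate autoregressive (MVAR) model
#'
#' Ordinary-least-squares estimation, equation by equation, of
#' `x_t = sum_{k=1..p} A_k x_{t-k} + e_t` on a multichannel series. This is
#' the model underlying Granger-causal inference: coefficient `A_k[i, j]`
#' carries the lag-`k` influence of channel `j` on channel `i`, and the
#' residual covariance supplies the innovation variances that weight the
#' GPDC spectrum.
#'
#' Channels are z-scored before fitting by default, which makes the
#' innovation-variance weighting comparable across networks. If `ts` carries
#' a `censor_mask` attribute (see [censor_outliers()]), the model is fitted
#' on the longest contiguous run of uncensored frames.
#'
#' @param ts `T x N` series matrix; column names become channel names.
#' @param order VAR lag order `p >= 1`.
#' @param standardize z-score each channel first (default TRUE).
#' @param aic_window fit on the sample window implied by this maximal order
#'   (used by [select_order_aic()] so candidate orders share a window);
#'   default `order`.
#' @return an object of class `mvar`: `order`, `coeffs` (list of `p`
#'   `N x N` matrices, source = column, target = row), `residual_cov`
#'   (small-sample divisor `T_eff - N p - 1`), `noise_vars` (its diagonal),
#'   `residuals`, `fitted`, `n_samples_used`, `channel_names`,
#'   `sampling_interval`, `logdet_ml` (log-determinant of the ML residual
#'   covariance, used by AIC).
#' @examples
#' g <- default_study_graph()
#' x <- simulate_var(g, 500, seed = 1)
#' fit <- mvar(x, order = 1)
#' round(coef(fit)[[1]], 2)
#' @export
mvar <- function(ts, order, standardize = TRUE, aic_window = order) {
  stopifnot(is.matrix(ts))
  if (order < 1L) stop("VAR order must be >= 1")
  if (aic_window < order) stop("`aic_window` must be >= `order`")
  mask <- attr(ts, "censor_mask")
  if (!is.null(mask)) {
    run <- longest_keep_run(mask$keep)
    tr_attr <- attr(ts, "sampling_interval")
    ts <- ts[run, , drop = FALSE]
    attr(ts, "sampling_interval") <- tr_attr
  }
  n <- ncol(ts)
  t_total <- nrow(ts)
  t_eff <- t_total - aic_window
  if (t_eff <= n * order + 1L)
    stop(sprintf(
      "not identifiable: %d effective samples for %d parameters per equation",
      t_eff, n * order + 1L))
  x <- if (standardize) scale(ts) else scale(ts, scale = FALSE)
  y <- x[(aic_window + 1L):t_total, , drop = FALSE]
  lagged <- do.call(cbind, lapply(seq_len(order), function(k)
    x[(aic_window + 1L - k):(t_total - k), , drop = FALSE]))
  gram <- crossprod(lagged)
  b <- tryCatch(
    solve(gram, crossprod(lagged, y)),
    error = function(e) {
      warning("singular regressor Gram matrix; adding ridge jitter 1e-8")
      solve(gram + diag(1e-8, ncol(gram)), crossprod(lagged, y))
    })
  fitted <- lagged %*% b
  resid <- y - fitted
  df_resid <- t_eff - n * order - 1L
  sigma <- crossprod(resid) / df_resid
  sigma_ml <- crossprod(resid) / t_eff
  nm <- colnames(ts)
  if (is.null(nm)) nm <- paste0("X", seq_len(n))
  coeffs <- lapply(seq_len(order), function(k) {
    a <- t(b[(k - 1L) * n + seq_len(n), , drop = FALSE])
    dimnames(a) <- list(nm, nm)
    a
  })
  dimnames(sigma) <- list(nm, nm)
  structure(
    list(order = as.integer(order), coeffs = coeffs, residual_cov = sigma,
         noise_vars = diag(sigma), residuals = resid, fitted = fitted,
         n_samples_used = t_eff, channel_names = nm,
         sampling_interval = attr(ts, "sampling_interval"),
         logdet_ml = determinant(sigma_ml, logarithm = TRUE)$modulus[[1L]],
         standardize = standardize),
    class = "mvar")
}

#' Select the VAR order by the Akaike information criterion
#'
#' Fits orders `1..p_max` on the common sample window implied by `p_max` and
#' returns the minimizer of the multivariate AIC
#' `ln det(Sigma_ML) + 2 p N^2 / T_eff`; ties resolve to the smallest
#' order.
#'
#' @param ts `T x N` series matrix.
#' @param p_max maximal candidate order.
#' @param standardize passed to [mvar()].
#' @return the selected order, with the AIC values over the candidate
#'   orders attached as attribute `aic`.
#' @export
select_order_aic <- function(ts, p_max = 6L, standardize = TRUE) {
  stopifnot(p_max >= 1L)
  n <- ncol(ts)
  aic <- vapply(seq_len(p_max), function(p) {
    fit <- mvar(ts, p, standardize = standardize, aic_window = p_max)
    fit$logdet_ml + 2 * p * n^2 / fit$n_samples_used
  }, numeric(1L))
  structure(which.min(aic), aic = aic)
}

#' @export
print.mvar <- function(x, ...) {
  cat(sprintf("MVAR(%d) fit: %d channels, %d samples used\n",
              x$order, length(x$channel_names), x$n_samples_used))
  cat("Channels:", paste(x$channel_names, collapse = ", "), "\n")
  cat(sprintf("Innovation variances: %s\n",
              paste(sprintf("%.3f", x$noise_vars), collapse = ", ")))
  invisible(x)
}

#' @export
coef.mvar <- function(object, ...) object$coeffs

#' @export
residuals.mvar <- function(object, ...) object$residuals

#' @export
summary.mvar <- function(object, ...) {
  out <- list(fit = object,
              spectral_radius = spectral_radius(object),
              logdet_ml = object$logdet_ml)
  class(out) <- "summary.mvar"
  out
}

#' @export
print.summary.mvar <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Spectral radius of companion matrix: %.3f\n",
              x$spectral_radius))
  for (k in seq_along(x$fit$coeffs)) {
    cat(sprintf("A_%d (source = column, target = row):\n", k))
    print(round(x$fit$coeffs[[k]], 3))
  }
  invisible(x)
}

#' One-step-ahead prediction from a fitted MVAR model
#'
#' @param object an [mvar()] fit.
#' @param newdata `T x N` matrix on the scale the model was fitted on
#'   (z-scored channels if `standardize` was TRUE).
#' @param ... unused.
#' @return `(T - p) x N` matrix of one-step predictions aligned with rows
#'   `p+1 .. T` of `newdata`.
#' @export
predict.mvar <- function(object, newdata, ...) {
  p <- object$order
  n <- length(object$channel_names)
  stopifnot(is.matrix(newdata), ncol(newdata) == n, nrow(newdata) > p)
  t_total <- nrow(newdata)
  pred <- matrix(0, t_total - p, n)
  for (k in seq_len(p))
    pred <- pred + newdata[(p + 1L - k):(t_total - k), , drop = FALSE] %*%
      t(object$coeffs[[k]])
  colnames(pred) <- object$channel_names
  pred
}

#' Simulate new series from a fitted MVAR model
#'
#' @param object an [mvar()] fit.
#' @param nsim number of timepoints.
#' @param seed integer seed.
#' @param ... unused.
#' @return `nsim x N` series matrix (burn-in of 500 discarded).
#' @export
simulate.mvar <- function(object, nsim = 500L, seed = NULL, ...) {
  g <- causal_graph(object$coeffs, pmax(object$noise_vars, 1e-12),
                    object$channel_names)
  simulate_var(g, nsim, seed = seed,
               tr_seconds = object$sampling_interval %||% 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
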