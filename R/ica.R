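#' Estimate the number of signal components by MDL
#'
#' Classical minimum-description-length estimate of signal subspace
#' dimension from the eigenvalues of the sample covariance: for each
#' candidate `q` the likelihood term is `-n (m - q) ln(GM_q / AM_q)` with
#' `GM_q`/`AM_q` the geometric/arithmetic means of the `m - q` smallest
#' eigenvalues, and the penalty is `q (2m - q) ln(n) / 2` for `m` channels
#' and `n` samples. Returns the minimizing `q`.
#'
#' @param data `n x m` matrix, rows = observations (e.g. voxels), columns =
#'   channels (e.g. timepoints).
#' @return estimated component count (integer in `0 .. m - 1`), with the
#'   MDL curve attached as attribute `mdl`.
#' @export
estimate_ncomp_mdl <- function(data) {
  stopifnot(is.matrix(data))
  n <- nrow(data)
  m <- ncol(data)
  if (n <= m) stop("need more observations (rows) than channels (columns)")
  ev <- sort(eigen(stats::cov(data), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  floor_val <- max(ev) * 1e-12
  if (any(ev < floor_val)) {
    warning("degenerate covariance: flooring near-zero eigenvalues")
    ev <- pmax(ev, floor_val)
  }
  qs <- 0:(m - 1L)
  mdl <- vapply(qs, function(q) {
    tail_ev <- ev[(q + 1L):m]
    gm <- mean(log(tail_ev))
    am <- log(mean(tail_ev))
    -n * (m - q) * (gm - am) + q * (2 * m - q) * log(n) / 2
  }, numeric(1L))
  structure(qs[which.min(mdl)], mdl = mdl)
}

# symmetric fixed-point ICA (tanh contrast) on whitened data z (q x samples);
# returns the orthogonal unmixing matrix w (q x q)
fastica_core <- function(z, w0, max_iter = 300L, tol = 1e-7) {
  orthonormalize <- function(w) {
    s <- svd(w)
    s$u %*% t(s$v)
  }
  w <- orthonormalize(w0)
  n_samp <- ncol(z)
  for (it in seq_len(max_iter)) {
    wz <- w %*% z
    g <- tanh(wz)
    gprime <- rowMeans(1 - g^2)
    w_new <- g %*% t(z) / n_samp - gprime * w
    w_new <- orthonormalize(w_new)
    delta <- max(abs(abs(diag(w_new %*% t(w))) - 1))
    w <- w_new
    if (delta < tol) return(list(w = w, iterations = it, converged = TRUE))
  }
  list(w = w, iterations = max_iter, converged = FALSE)
}

# match columns/rows of two component sets by greedy maximal |correlation|;
# returns for each row of `a` the index of its match in `b` and the |r|
match_components <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  cors <- abs(stats::cor(t(a), t(b)))
  k <- nrow(a)
  pairs <- integer(k)
  score <- numeric(k)
  used_a <- used_b <- rep(FALSE, k)
  for (step in seq_len(k)) {
    cors_masked <- cors
    cors_masked[used_a, ] <- -Inf
    cors_masked[, used_b] <- -Inf
    ij <- which(cors_masked == max(cors_masked), arr.ind = TRUE)[1L, ]
    pairs[ij[1L]] <- ij[2L]
    score[ij[1L]] <- cors[ij[1L], ij[2L]]
    used_a[ij[1L]] <- used_b[ij[2L]] <- TRUE
  }
  list(match = pairs, abs_cor = score)
}

#' Temporal-concatenation group spatial ICA with dual regression
#'
#' Each subject-session image is voxelwise demeaned and variance-normalized,
#' all are temporally concatenated, the concatenated data are PCA-reduced to
#' `n_components` and whitened, and a symmetric fixed-point ICA (tanh
#' contrast) unmixes them into spatial component maps. The decomposition is
#' run from `n_restarts` random initializations; the restart whose
#' components are most consistently recovered across all restarts (highest
#' mean matched absolute correlation) is kept. Subject-specific time courses
#' and maps are then recovered by dual regression against the group maps.
#'
#' @param images list of `voxel_image` objects (`T x V` matrices with a
#'   `dims` attribute) sharing one grid, e.g. from [render_voxels()] or the
#'   nested `images` element of [generate_study()] flattened to a list.
#' @param n_components number of components; if `NULL`, estimated by
#'   [estimate_ncomp_mdl()] on the concatenated data.
#' @param n_restarts random restarts for stability selection.
#' @param seed integer seed.
#' @param max_iter,tol fixed-point iteration controls.
#' @return an object of class `ica_decomposition`: `n_components`,
#'   `group_maps` (`n_components x V`, z-scored rows, `dims` attribute),
#'   `timecourses` (list per image, `T x n_components`), `subject_maps`
#'   (list per image, `n_components x V`), `stability` (per-restart score),
#'   `converged`, `dims`.
#' @export
fit_group_ica <- function(images, n_components = NULL, n_restarts = 5L,
                          seed = 1L, max_iter = 300L, tol = 1e-7) {
  stopifnot(length(images) >= 1L)
  dims <- attr(images[[1L]], "dims")
  v <- ncol(images[[1L]])
  if (!all(vapply(images, ncol, integer(1L)) == v))
    stop("all images must share one voxel grid")
  set.seed(seed)
  # voxelwise demean, then one global variance scale per image: per-voxel
  # z-scoring would distort the spatial profiles the decomposition recovers
  norm_one <- function(img) {
    x <- scale(unclass(img), scale = FALSE)
    x / stats::sd(x)
  }
  x_cat <- do.call(rbind, lapply(images, norm_one))
  if (is.null(n_components))
    # voxels are the observations, concatenated timepoints the channels
    n_components <- max(1L, as.integer(estimate_ncomp_mdl(t(x_cat))))
  sv <- svd(x_cat, nu = n_components, nv = 0)
  if (n_components > length(sv$d))
    stop("`n_components` exceeds the reduced dimension")
  # whitened q x V data: rows unit-variance uncorrelated voxel patterns
  z <- t(sv$u[, seq_len(n_components), drop = FALSE]) %*% x_cat *
    sqrt(v / nrow(x_cat))
  z <- z / sqrt(rowMeans(z^2))
  runs <- lapply(seq_len(n_restarts), function(r) {
    w0 <- matrix(stats::rnorm(n_components^2), n_components)
    fastica_core(z, w0, max_iter = max_iter, tol = tol)
  })
  if (!any(vapply(runs, `[[`, logical(1L), "converged")))
    stop(sprintf(
      "no ICA restart converged within %d iterations (best delta across %d restarts)",
      max_iter, n_restarts))
  sources <- lapply(runs, function(r) r$w %*% z)
  stability <- vapply(seq_len(n_restarts), function(r) {
    others <- setdiff(seq_len(n_restarts), r)
    if (length(others) == 0L) return(1)
    mean(vapply(others, function(o)
      mean(match_components(sources[[r]], sources[[o]])$abs_cor),
      numeric(1L)))
  }, numeric(1L))
  best <- which.max(stability)
  maps <- sources[[best]]
  maps <- maps / apply(maps, 1L, stats::sd)   # z-score rows
  maps <- sweep(maps, 1L, rowMeans(maps))
  # dual regression: maps -> time courses -> subject maps
  gm_t <- t(maps)
  tcs <- lapply(images, function(img)
    qr.coef(qr(gm_t), t(norm_one(img))) |> t())
  smaps <- mapply(function(img, tc)
    qr.coef(qr(tc), norm_one(img)),
    images, tcs, SIMPLIFY = FALSE)
  attr(maps, "dims") <- dims
  structure(
    list(n_components = n_components, group_maps = maps,
         timecourses = tcs, subject_maps = smaps,
         stability = stability, best_restart = best,
         converged = vapply(runs, `[[`, logical(1L), "converged"),
         dims = dims),
    class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf(
    "Group ICA: %d components, %d subject-session images, grid %s\n",
    x$n_components, length(x$timecourses),
    paste(x$dims, collapse = "x")))
  cat(sprintf("Restart stability: %s (kept restart %d)\n",
              paste(sprintf("%.3f", x$stability), collapse = ", "),
              x$best_restart))
  invisible(x)
}

#' Template goodness of fit of a spatial map
#'
#' Mean map value inside the binary template minus the mean outside —
#' the standard template-matching score for labelling ICA components as
#' named resting-state networks.
#'
#' @param map numeric voxel vector (typically a z-scored component map).
#' @param template binary (0/1 or logical) vector on the same grid.
#' @return the score (scalar).
#' @export
goodness_of_fit <- function(map, template) {
  map <- as.numeric(map)
  template <- as.logical(template)
  if (length(map) != length(template))
    stop("map and template must share the grid")
  if (!any(template) || all(template))
    stop("template must be non-empty and not cover the whole grid")
  mean(map[template]) - mean(map[!template])
}

#' Assign network labels to ICA components by template matching
#'
#' Greedy assignment: the highest goodness-of-fit (component, template)
#' pair is labelled first, both are removed, and the process repeats. Ties
#' resolve to the lower component index. A warning flags any label whose
#' best available score is not positive.
#'
#' @param dec an [fit_group_ica()] decomposition.
#' @param templates named list of binary template vectors on the
#'   decomposition's grid.
#' @return data.frame with columns `network`, `component`, `score`, ordered
#'   as the templates.
#' @export
assign_networks <- function(dec, templates) {
  stopifnot(inherits(dec, "ica_decomposition"), length(templates) >= 1L)
  if (dec$n_components < length(templates))
    stop("fewer components than templates")
  gof <- sapply(templates, function(tpl)
    apply(dec$group_maps, 1L, goodness_of_fit, template = tpl))
  gof <- matrix(gof, nrow = dec$n_components,
                dimnames = list(NULL, names(templates)))
  n_lab <- length(templates)
  res <- data.frame(network = names(templates),
                    component = NA_integer_, score = NA_real_)
  used_comp <- rep(FALSE, dec$n_components)
  used_lab <- rep(FALSE, n_lab)
  for (step in seq_len(n_lab)) {
    g <- gof
    g[used_comp, ] <- -Inf
    g[, used_lab] <- -Inf
    ij <- which(g == max(g), arr.ind = TRUE)
    ij <- ij[order(ij[, 1L]), , drop = FALSE][1L, ]  # tie: lower component
    res$component[ij[2L]] <- ij[1L]
    res$score[ij[2L]] <- gof[ij[1L], ij[2L]]
    used_comp[ij[1L]] <- TRUE
    used_lab[ij[2L]] <- TRUE
  }
  if (any(res$score <= 0))
    warning(sprintf("dubious assignment (score <= 0) for: %s",
                    paste(res$network[res$score <= 0], collapse = ", ")))
  res
}
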