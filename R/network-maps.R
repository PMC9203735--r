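#' Fisher r-to-z transformation
#'
#' Variance-stabilizing transform `z = atanh(r)` applied to correlations
#' before parametric map statistics.
#'
#' @param r correlations, strictly inside `(-1, 1)`.
#' @return z values, same shape.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE))
    stop("Fisher z is undefined for |r| >= 1")
  atanh(r)
}

# voxelwise one-sample t of a subjects x voxels matrix against 0;
# zero-variance voxels get t = 0 and are reported in the mask
voxel_t_onesample <- function(x) {
  n <- nrow(x)
  if (n < 2L) {
    t_stat <- rep(0, ncol(x))
    return(list(t = t_stat, df = n - 1L, mask = rep(FALSE, ncol(x))))
  }
  m <- colMeans(x)
  v <- (colSums(x^2) - n * m^2) / (n - 1L)
  ok <- v > 0
  t_stat <- rep(0, ncol(x))
  t_stat[ok] <- m[ok] / sqrt(v[ok] / n)
  list(t = t_stat, df = n - 1L, mask = ok)
}

# voxelwise pooled-variance two-sample t (group a minus group b)
voxel_t_twosample <- function(x, is_a) {
  na <- sum(is_a); nb <- sum(!is_a)
  stopifnot(na >= 2L, nb >= 2L)
  ma <- colMeans(x[is_a, , drop = FALSE])
  mb <- colMeans(x[!is_a, , drop = FALSE])
  va <- apply(x[is_a, , drop = FALSE], 2L, stats::var)
  vb <- apply(x[!is_a, , drop = FALSE], 2L, stats::var)
  sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
  ok <- sp2 > 0
  t_stat <- rep(0, length(ma))
  t_stat[ok] <- (ma[ok] - mb[ok]) / sqrt(sp2[ok] * (1 / na + 1 / nb))
  list(t = t_stat, df = na + nb - 2L, mask = ok)
}

#' Voxelwise condition effect (after vs before)
#'
#' Paired t statistic of the per-subject session difference
#' (after minus before) at every voxel. Positive t = increase after the
#' intervention. Zero-variance voxels are set to 0 and masked out.
#'
#' @param before,after `n_subjects x n_voxels` matrices of Fisher-z maps,
#'   rows aligned by subject.
#' @return list with `t` (voxel vector), `df`, `mask` (TRUE where the
#'   statistic is defined), `diffs` (the per-subject difference maps, for
#'   [cluster_fwe()]).
#' @export
condition_effect <- function(before, after) {
  stopifnot(is.matrix(before), is.matrix(after),
            all(dim(before) == dim(after)))
  d <- after - before
  out <- voxel_t_onesample(d)
  out$diffs <- d
  out
}

#' Voxelwise interaction effect (patients vs controls change)
#'
#' Two-sample pooled-variance t on the per-subject (after minus before)
#' difference maps, patients minus controls: positive t = the change is
#' larger in patients.
#'
#' @param before,after `n_subjects x n_voxels` matrices, rows aligned.
#' @param group character/factor per subject with levels containing
#'   `"patient"` and `"control"` (any two labels; the first level given in
#'   `positive` is the minuend).
#' @param positive the group whose larger change yields positive t.
#' @return list with `t`, `df`, `mask`, `diffs`, `group`.
#' @export
interaction_effect <- function(before, after, group, positive = "patient") {
  stopifnot(nrow(before) == length(group))
  is_a <- group == positive
  if (sum(is_a) < 2L || sum(!is_a) < 2L)
    stop("each group needs at least 2 subjects")
  d <- after - before
  out <- voxel_t_twosample(d, is_a)
  out$diffs <- d
  out$group <- group
  out
}

# 26-connectivity connected components of a set of voxels.
# idx: 1-based linear indices into a grid of dimension `dims`.
# Returns an integer component label per element of idx.
label_components_26 <- function(idx, dims) {
  k <- length(idx)
  if (k == 0L) return(integer(0))
  ord <- order(idx)
  sidx <- idx[ord]
  pos <- arrayInd(sidx, dims)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  strides <- c(1L, dims[1L], dims[1L] * dims[2L])
  for (o in seq_len(nrow(offsets))) {
    np <- sweep(pos, 2L, offsets[o, ], "+")
    valid <- np[, 1L] >= 1L & np[, 1L] <= dims[1L] &
      np[, 2L] >= 1L & np[, 2L] <= dims[2L] &
      np[, 3L] >= 1L & np[, 3L] <= dims[3L]
    if (!any(valid)) next
    nlin <- (np[valid, , drop = FALSE] - 1L) %*% strides + 1L
    j <- match(nlin, sidx)
    hit <- which(!is.na(j))
    from <- which(valid)[hit]
    to <- j[hit]
    for (e in seq_along(from)) {
      ra <- find(from[e]); rb <- find(to[e])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(k), find, integer(1L))
  labels <- match(roots, unique(roots))
  labels[order(ord)]
}

# max cluster extent among suprathreshold voxels of one t map
max_cluster_extent <- function(t_vec, thresh, dims) {
  idx <- which(abs(t_vec) > thresh)
  if (length(idx) == 0L) return(0L)
  max(tabulate(label_components_26(idx, dims)))
}

#' Cluster-level FWE correction by permutation
#'
#' Forms clusters of voxels whose |t| exceeds the two-tailed
#' cluster-forming threshold (`p_form`, default 0.005) under
#' 26-connectivity, and corrects their extent at the cluster level against
#' a permutation null of the maximal cluster extent: sign-flipping of the
#' per-subject difference maps for the condition effect, group-label
#' permutation for the interaction effect. The corrected p-value is
#' `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param effect a [condition_effect()] or [interaction_effect()] result
#'   (must carry `diffs`, and `group` for the interaction).
#' @param dims 3D grid dimensions of the voxel maps.
#' @param p_form two-tailed cluster-forming p threshold.
#' @param p_fwe cluster-level familywise significance level.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return an object of class `cluster_result`: data.frame `clusters`
#'   (label, extent, peak_t, peak_x/y/z, p_fwe, significant), the threshold
#'   used, the permutation null (`null_max_extent`), and the voxelwise
#'   cluster labelling (`labels`, 0 = subthreshold).
#' @export
cluster_fwe <- function(effect, dims, p_form = 0.005, p_fwe = 0.05,
                        n_perm = 1000L, seed = 1L) {
  stopifnot(!is.null(effect$diffs), n_perm >= 100L)
  d <- effect$diffs
  n_sub <- nrow(d)
  if (n_sub < 10L)
    stop("fewer than 10 permutable subjects; use exact enumeration instead")
  thresh <- stats::qt(1 - p_form / 2, df = effect$df)
  set.seed(seed)
  v <- ncol(d)
  interaction <- !is.null(effect$group)
  # observed clusters
  obs_idx <- which(abs(effect$t) > thresh & effect$mask)
  labels_vec <- integer(v)
  clusters <- data.frame(label = integer(0), extent = integer(0),
                         peak_t = numeric(0), peak_x = integer(0),
                         peak_y = integer(0), peak_z = integer(0))
  if (length(obs_idx) > 0L) {
    lab <- label_components_26(obs_idx, dims)
    labels_vec[obs_idx] <- lab
    for (cl in seq_len(max(lab))) {
      vox <- obs_idx[lab == cl]
      pk <- vox[which.max(abs(effect$t[vox]))]
      pc <- arrayInd(pk, dims)
      clusters[cl, ] <- list(cl, length(vox), effect$t[pk],
                             pc[1L], pc[2L], pc[3L])
    }
  }
  # permutation null of the maximal extent
  if (interaction) {
    is_a <- effect$group == unique(effect$group)[1L]
    null_max <- vapply(seq_len(n_perm), function(pp) {
      perm <- sample(is_a)
      tt <- voxel_t_twosample(d, perm)
      max_cluster_extent(tt$t, thresh, dims)
    }, integer(1L))
  } else {
    ss <- colSums(d^2)
    signs <- matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE),
                    n_perm, n_sub)
    m <- signs %*% d / n_sub
    vvar <- sweep(-n_sub * m^2, 2L, ss, "+") / (n_sub - 1L)
    tmat <- m / sqrt(pmax(vvar, .Machine$double.eps) / n_sub)
    null_max <- vapply(seq_len(n_perm), function(pp)
      max_cluster_extent(tmat[pp, ], thresh, dims), integer(1L))
  }
  if (nrow(clusters) > 0L) {
    clusters$p_fwe <- vapply(clusters$extent, function(e)
      (1 + sum(null_max >= e)) / (1 + n_perm), numeric(1L))
    clusters$significant <- clusters$p_fwe < p_fwe
    clusters <- clusters[order(-clusters$extent), ]
  } else {
    clusters$p_fwe <- numeric(0)
    clusters$significant <- logical(0)
  }
  structure(list(clusters = clusters, threshold = thresh, p_form = p_form,
                 p_fwe = p_fwe, n_perm = n_perm,
                 null_max_extent = null_max, labels = labels_vec,
                 dims = dims),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "Cluster inference: |t| > %.2f (two-tailed p = %g), %d permutations\n",
    x$threshold, x$p_form, x$n_perm))
  if (nrow(x$clusters) == 0L) {
    cat("No suprathreshold clusters.\n")
  } else {
    print(x$clusters, row.names = FALSE)
  }
  invisible(x)
}
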