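#' Study table of edge matrices and metadata
#'
#' Binds per subject-session edge matrices with group/session labels and an
#' optional clinical-score table into the unit on which the edge-wise group
#' statistics and the clinical correlations operate.
#'
#' @param edges nested list `[[subject_id]][[session]]` of `N x N` edge
#'   matrices (band-averaged GPDC, source = column, target = row).
#' @param subjects data.frame with `subject_id` and `group`.
#' @param clinical optional long data.frame with `subject_id`, `session` and
#'   score columns.
#' @return an object of class `study_table`.
#' @export
study_table <- function(edges, subjects, clinical = NULL) {
  stopifnot(all(names(edges) %in% subjects$subject_id))
  n_set <- unique(unlist(lapply(edges, function(e)
    vapply(e, nrow, integer(1L)))))
  if (length(n_set) != 1L)
    stop("inconsistent edge-matrix dimension across subjects")
  structure(list(edges = edges, subjects = subjects, clinical = clinical,
                 n_nodes = n_set,
                 node_names = rownames(edges[[1L]][[1L]])),
            class = "study_table")
}

#' Build a study table by running the causal pipeline on a study
#'
#' Band-pass filters every subject-session series, selects one common VAR
#' order (the modal AIC choice across subject-sessions, for comparability),
#' and computes the band-averaged GPDC edge matrix for each.
#'
#' @param study a [generate_study()] result (or compatible list).
#' @param band frequency band in Hz.
#' @param p_max maximal candidate VAR order.
#' @param order fixed VAR order; if `NULL`, the modal AIC selection.
#' @param filter band-pass filter the series first (default TRUE).
#' @return a [study_table()], with the order used attached as attribute
#'   `order`.
#' @export
compute_edge_tables <- function(study, band = c(0.01, 0.1), p_max = 6L,
                                order = NULL, filter = TRUE) {
  series <- study$series
  prep <- lapply(series, function(sess_list)
    lapply(sess_list, function(x)
      if (filter) bandpass(x, band[1L], band[2L]) else x))
  if (is.null(order)) {
    orders <- unlist(lapply(prep, function(sl)
      lapply(sl, function(x) as.integer(select_order_aic(x, p_max)))))
    tab <- table(orders)
    order <- as.integer(names(tab)[which.max(tab)])
  }
  edges <- lapply(prep, function(sl)
    lapply(sl, function(x) edge_matrix(x, order = order, band = band)))
  out <- study_table(edges, study$subjects, study$clinical)
  attr(out, "order") <- order
  out
}

# stack selected edge matrices into a subjects x edges matrix
# (off-diagonal directed edges only)
stack_edges <- function(table, group = NULL, session) {
  subs <- table$subjects
  if (!is.null(group)) subs <- subs[subs$group %in% group, , drop = FALSE]
  ids <- subs$subject_id
  n <- table$n_nodes
  off <- which(diag(n) == 0)
  m <- t(vapply(ids, function(id)
    table$edges[[id]][[session]][off], numeric(length(off))))
  src <- col(diag(n))[off]
  tgt <- row(diag(n))[off]
  nm <- table$node_names
  list(values = m, ids = ids,
       edge_names = data.frame(source = nm[src], target = nm[tgt]),
       off = off)
}

edge_test_result <- function(edge_names, t_stat, pvals, q_level, extra = NULL) {
  qvals <- stats::p.adjust(pvals, method = "BH")
  out <- cbind(edge_names,
               data.frame(t = t_stat, p = pvals, q = qvals,
                          significant = qvals < q_level))
  if (!is.null(extra)) out <- cbind(out, extra)
  class(out) <- c("edge_test_result", class(out))
  attr(out, "q_level") <- q_level
  out
}

#' One-sample edge test
#'
#' Per directed off-diagonal edge, a one-sample t test of the edge values
#' against zero across the selected subjects, BH-FDR corrected across the
#' `N(N-1)` edges.
#'
#' @param table a [study_table()].
#' @param group group label(s) to include (`NULL` = all).
#' @param session session label.
#' @param q FDR level.
#' @return an `edge_test_result` data.frame: `source`, `target`, `t`, `p`,
#'   `q`, `significant`, `mean`.
#' @export
one_sample_edges <- function(table, group = NULL, session = "before",
                             q = 0.05) {
  s <- stack_edges(table, group, session)
  if (nrow(s$values) < 3L) stop("need at least 3 subjects")
  stats_per_edge <- apply(s$values, 2L, function(x) {
    if (stats::sd(x) == 0) {
      message("zero-variance edge: p set to 1")
      return(c(t = 0, p = 1))
    }
    tt <- stats::t.test(x)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  edge_test_result(s$edge_names, stats_per_edge["t", ],
                   stats_per_edge["p", ], q,
                   extra = data.frame(mean = colMeans(s$values)))
}

#' Independent two-sample edge test (patients vs controls)
#'
#' Per edge, a pooled-variance two-sample t test of patients against
#' controls at one session (positive t = patients higher), BH-FDR corrected
#' across edges.
#'
#' @param table a [study_table()].
#' @param session session label.
#' @param q FDR level.
#' @param welch use the Welch statistic instead of pooled variance.
#' @return an `edge_test_result` with group means appended.
#' @export
independent_t_edges <- function(table, session = "before", q = 0.05,
                                welch = FALSE) {
  pat <- stack_edges(table, "patient", session)
  ctl <- stack_edges(table, "control", session)
  if (nrow(pat$values) < 2L || nrow(ctl$values) < 2L)
    stop("both groups need at least 2 subjects")
  stats_per_edge <- vapply(seq_len(ncol(pat$values)), function(e) {
    tt <- stats::t.test(pat$values[, e], ctl$values[, e],
                        var.equal = !welch)
    c(unname(tt$statistic), tt$p.value)
  }, numeric(2L))
  edge_test_result(pat$edge_names, stats_per_edge[1L, ],
                   stats_per_edge[2L, ], q,
                   extra = data.frame(mean_patient = colMeans(pat$values),
                                      mean_control = colMeans(ctl$values)))
}

#' Paired edge test (after vs before)
#'
#' Per edge, a paired t test of the within-subject session difference
#' (after minus before) in one group, BH-FDR corrected across edges.
#' Subjects missing either session are excluded with a message.
#'
#' @param table a [study_table()].
#' @param group group label.
#' @param q FDR level.
#' @return an `edge_test_result` with the mean difference appended.
#' @export
paired_t_edges <- function(table, group = "patient", q = 0.05) {
  subs <- table$subjects
  ids <- subs$subject_id[subs$group == group]
  complete <- vapply(ids, function(id)
    all(c("before", "after") %in% names(table$edges[[id]])), logical(1L))
  if (any(!complete))
    message("excluding unpaired subject(s): ",
            paste(ids[!complete], collapse = ", "))
  ids <- ids[complete]
  if (length(ids) < 3L) stop("need at least 3 paired subjects")
  n <- table$n_nodes
  off <- which(diag(n) == 0)
  d <- t(vapply(ids, function(id)
    (table$edges[[id]][["after"]] - table$edges[[id]][["before"]])[off],
    numeric(length(off))))
  nm <- table$node_names
  edge_names <- data.frame(source = nm[col(diag(n))[off]],
                           target = nm[row(diag(n))[off]])
  stats_per_edge <- apply(d, 2L, function(x) {
    if (stats::sd(x) == 0) return(c(0, 1))
    tt <- stats::t.test(x)
    c(unname(tt$statistic), tt$p.value)
  })
  edge_test_result(edge_names, stats_per_edge[1L, ], stats_per_edge[2L, ],
                   q, extra = data.frame(mean_diff = colMeans(d)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values and significance flags at level `q`.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param q FDR level.
#' @return list with `qvals` and `flags`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  qvals <- stats::p.adjust(pvals, method = "BH")
  list(qvals = qvals, flags = qvals < q)
}

#' Edge-occurrence frequency map
#'
#' Entrywise mean of per-subject binary detection matrices: the fraction of
#' subjects in which each directed edge was detected.
#'
#' @param detections list of `N x N` logical/0-1 matrices (diagonal may be
#'   `NA`).
#' @return `N x N` matrix of proportions in `[0, 1]`.
#' @export
edge_frequency <- function(detections) {
  stopifnot(length(detections) >= 1L)
  dims <- vapply(detections, dim, integer(2L))
  if (length(unique(dims[1L, ])) != 1L || length(unique(dims[2L, ])) != 1L)
    stop("inconsistent detection-matrix dimension")
  Reduce(`+`, lapply(detections, function(m) {
    m[is.na(m)] <- 0
    m * 1
  })) / length(detections)
}

#' Correlation between causal strength of an edge and a clinical score
#'
#' Pearson correlation (with the exact t-based two-tailed p, df = n - 2)
#' between the band-averaged GPDC of one directed edge and a clinical score
#' across subjects. `mode = "levels"` correlates the values at one session;
#' `mode = "differences"` correlates per-subject (after - before) changes in
#' both variables.
#'
#' @param table a [study_table()] with a clinical table attached.
#' @param edge directed edge `c(source, target)` node names.
#' @param score clinical score column name.
#' @param group group label (default `"patient"`).
#' @param session session for `mode = "levels"`.
#' @param mode `"levels"` or `"differences"`.
#' @return list with `r`, `r_squared`, `p`, `n`, `slope`, `intercept` (of
#'   the least-squares line score ~ edge), and the paired vectors `edge_values`,
#'   `score_values`.
#' @export
edge_score_correlation <- function(table, edge, score, group = "patient",
                                   session = "after",
                                   mode = c("levels", "differences")) {
  mode <- match.arg(mode)
  if (is.null(table$clinical)) stop("study table has no clinical scores")
  subs <- table$subjects
  ids <- subs$subject_id[subs$group == group]
  cl <- table$clinical
  get_edge <- function(id, sess) table$edges[[id]][[sess]][edge[2L], edge[1L]]
  get_score <- function(id, sess)
    cl[cl$subject_id == id & cl$session == sess, score][1L]
  if (mode == "levels") {
    x <- vapply(ids, get_edge, numeric(1L), sess = session)
    y <- vapply(ids, get_score, numeric(1L), sess = session)
  } else {
    x <- vapply(ids, function(id)
      get_edge(id, "after") - get_edge(id, "before"), numeric(1L))
    y <- vapply(ids, function(id)
      get_score(id, "after") - get_score(id, "before"), numeric(1L))
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: a variable is constant")
  ct <- stats::cor.test(x, y)
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       edge_values = x, score_values = y)
}
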