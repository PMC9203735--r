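#' Specification of a synthetic two-group, two-session study
#'
#' Describes the generative design the pipeline is validated against:
#' patients and controls, each scanned before and after an intervention.
#' At baseline patients have one designated directed edge attenuated
#' (multiplied by `patient_edge_deficit`); after the intervention the same
#' edge is additionally multiplied by `training_edge_gain` in patients only.
#' Controls use the base graph in both sessions. Clinical scores are a
#' linear function of that edge's true band-averaged GPDC plus noise.
#'
#' @param n_patients,n_controls group sizes; defaults 21 and 19.
#' @param n_timepoints samples per session; default 400.
#' @param tr_seconds repetition time in seconds; default 2.
#' @param base_graph the control-group [causal_graph()];
#'   default [default_study_graph()].
#' @param edge designated directed edge as `c(source, target)` node names;
#'   default `c("SMN", "DMN")`.
#' @param patient_edge_deficit multiplicative attenuation of the edge in
#'   patients at baseline; default 0.3.
#' @param training_edge_gain multiplicative restoration applied on top of
#'   the deficit in patients after the intervention; default 3.
#' @param clinical_link named list of score definitions, each a list with
#'   `intercept`, `slope` (score units per unit GPDC) and `noise_sd`.
#'   Defaults define RP and BP on a 0-100 scale.
#' @param subject_edge_sd sd of the per-subject log-normal multiplier on
#'   the designated edge (biological between-subject variability, shared by
#'   both of a subject's sessions); default 0.15. Without it all subjects
#'   in a cell would share one true causal strength and the clinical
#'   correlation would have no signal to recover.
#' @param outlier_frac fraction of frames whose simulated FD/DVARS exceed
#'   the motion-outlier thresholds; default 0.02.
#' @param hrf logical; convolve series with the canonical HRF (off by
#'   default so VAR structure is directly recoverable).
#' @param seed integer seed.
#' @return an object of class `study_spec`.
#' @export
study_spec <- function(n_patients = 21L, n_controls = 19L,
                       n_timepoints = 400L, tr_seconds = 2,
                       base_graph = default_study_graph(),
                       edge = c("SMN", "DMN"),
                       patient_edge_deficit = 0.3,
                       training_edge_gain = 3,
                       clinical_link = list(
                         RP = list(intercept = 30, slope = 150, noise_sd = 8),
                         BP = list(intercept = 45, slope = 110, noise_sd = 6)),
                       subject_edge_sd = 0.15,
                       outlier_frac = 0.02, hrf = FALSE, seed = 1L) {
  stopifnot(n_patients > 0L, n_controls > 0L, n_timepoints > 0L,
            tr_seconds > 0, patient_edge_deficit > 0, training_edge_gain > 0)
  if (!all(edge %in% base_graph$node_names))
    stop(sprintf("designated edge %s -> %s absent from base graph nodes",
                 edge[1L], edge[2L]))
  structure(
    list(n_patients = as.integer(n_patients),
         n_controls = as.integer(n_controls),
         n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
         base_graph = base_graph, edge = edge,
         patient_edge_deficit = patient_edge_deficit,
         training_edge_gain = training_edge_gain,
         clinical_link = clinical_link,
         subject_edge_sd = subject_edge_sd, outlier_frac = outlier_frac,
         hrf = hrf, seed = as.integer(seed)),
    class = "study_spec")
}

# scale the designated edge of a graph by `factor`
scale_edge <- function(graph, edge, factor) {
  a <- graph$coeffs
  a[[1L]][edge[2L], edge[1L]] <- a[[1L]][edge[2L], edge[1L]] * factor
  causal_graph(a, graph$noise_vars, graph$node_names)
}

#' True band-averaged GPDC of a causal graph
#'
#' Evaluates the GPDC spectrum implied by the graph's own coefficients and
#' innovation variances (no estimation) and averages it over a frequency
#' band. This is the ground-truth causal strength the synthetic clinical
#' scores are coupled to.
#'
#' @param graph a [causal_graph()].
#' @param tr_seconds sampling interval (seconds).
#' @param band frequency band in Hz, default `c(0.01, 0.1)`.
#' @param n_freqs frequency-grid size on `[0, Nyquist]`.
#' @return `N x N` matrix of band-averaged `|pi_ij|` (source = column,
#'   target = row).
#' @export
graph_gpdc <- function(graph, tr_seconds = 2, band = c(0.01, 0.1),
                       n_freqs = 129L) {
  model <- structure(
    list(order = graph$order, coeffs = graph$coeffs,
         residual_cov = diag(graph$noise_vars, graph$n_nodes),
         noise_vars = graph$noise_vars,
         channel_names = graph$node_names,
         sampling_interval = tr_seconds),
    class = "mvar")
  band_average(gpdc(model, n_freqs = n_freqs), band[1L], band[2L])
}

# simulated FD / DVARS confound table with a planted outlier fraction;
# outliers come in short bursts, as head-motion episodes do, so long
# contiguous clean runs remain for the VAR stage
simulate_confounds <- function(n_frames, outlier_frac, n_noise_voxels = 30L) {
  fd <- abs(stats::rnorm(n_frames, mean = 0.12, sd = 0.06))
  dv <- abs(stats::rnorm(n_frames, mean = 1.0, sd = 0.15))
  n_out <- round(outlier_frac * n_frames)
  idx <- integer(0)
  while (length(idx) < n_out) {
    start <- sample.int(n_frames, 1L)
    len <- 1L + stats::rpois(1L, 2)
    idx <- unique(c(idx, seq(start, min(n_frames, start + len - 1L))))
  }
  idx <- idx[seq_len(n_out)]
  if (n_out > 0L) {
    spike_fd <- idx[seq_len(ceiling(n_out / 2))]
    spike_dv <- idx[-seq_len(ceiling(n_out / 2))]
    fd[spike_fd] <- 0.5 + abs(stats::rnorm(length(spike_fd), 0.3, 0.2))
    dv[spike_dv] <- 1.5 + abs(stats::rnorm(length(spike_dv), 0.5, 0.3))
  }
  noise <- matrix(stats::rnorm(n_frames * n_noise_voxels), n_frames)
  colnames(noise) <- paste0("noise_voxel_", seq_len(n_noise_voxels))
  cbind(data.frame(framewise_displacement = fd, std_dvars = dv), noise)
}

#' Generate a synthetic two-group, two-session study
#'
#' Produces, fully reproducibly from the spec's seed, one complete study:
#' per subject-session network time courses simulated from the
#' subject-session's ground-truth graph, confound tables with a planted
#' motion-outlier fraction, and clinical scores linearly coupled to the true
#' causal strength of the designated edge in that session's graph.
#'
#' @param spec a [study_spec()].
#' @param voxels logical; additionally render voxel images (for the ICA
#'   stage) from blob maps. Off by default.
#' @param voxel_noise_sd,voxel_dims noise sd and grid for [render_voxels()].
#' @return an object of class `synthetic_study` with elements
#'   `subjects` (data.frame: subject_id, group), `series` (nested list
#'   `[[subject_id]][[session]]` of `T x N` matrices), `confounds` (same
#'   nesting), `clinical` (long data.frame subject_id, group, session, one
#'   column per score), `graphs` (same nesting, the per-subject-session
#'   ground truth), `true_edge_strength` (same nesting, scalar), `images`
#'   (if `voxels`), `maps` (planted spatial maps), and `spec`.
#' @export
generate_study <- function(spec, voxels = FALSE, voxel_noise_sd = 0.5,
                           voxel_dims = c(12L, 14L, 12L)) {
  stopifnot(inherits(spec, "study_spec"))
  set.seed(spec$seed)
  n_sub <- spec$n_patients + spec$n_controls
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n_sub)),
    group = rep(c("patient", "control"),
                c(spec$n_patients, spec$n_controls)),
    stringsAsFactors = FALSE)
  sessions <- c("before", "after")

  # per-subject biological variability of the designated edge, shared
  # across that subject's two sessions
  jitter <- exp(stats::rnorm(n_sub, sd = spec$subject_edge_sd))
  graph_for <- function(s, session) {
    factor <- if (subjects$group[s] == "control") 1
    else if (session == "before") spec$patient_edge_deficit
    else spec$patient_edge_deficit * spec$training_edge_gain
    scale_edge(spec$base_graph, spec$edge, factor * jitter[s])
  }

  maps <- if (voxels) blob_maps(spec$base_graph$n_nodes, voxel_dims)
  series <- confounds <- graphs <- truth <- images <- list()
  clin_rows <- list()
  for (s in seq_len(n_sub)) {
    id <- subjects$subject_id[s]
    series[[id]] <- list(); confounds[[id]] <- list()
    graphs[[id]] <- list(); truth[[id]] <- list()
    if (voxels) images[[id]] <- list()
    for (sess in sessions) {
      g <- graph_for(s, sess)
      sub_seed <- derive_seed(spec$seed, s * 2L + (sess == "after"))
      x <- simulate_var(g, spec$n_timepoints, seed = sub_seed,
                        tr_seconds = spec$tr_seconds)
      if (spec$hrf) x <- convolve_hrf(x)
      series[[id]][[sess]] <- x
      confounds[[id]][[sess]] <-
        simulate_confounds(spec$n_timepoints, spec$outlier_frac)
      graphs[[id]][[sess]] <- g
      edge_true <- graph_gpdc(g, spec$tr_seconds)[spec$edge[2L], spec$edge[1L]]
      truth[[id]][[sess]] <- edge_true
      if (voxels)
        images[[id]][[sess]] <- render_voxels(maps, x, voxel_noise_sd)
      scores <- lapply(spec$clinical_link, function(lnk)
        lnk$intercept + lnk$slope * edge_true +
          stats::rnorm(1L, sd = lnk$noise_sd))
      clin_rows[[length(clin_rows) + 1L]] <- cbind(
        data.frame(subject_id = id, group = subjects$group[s],
                   session = sess, stringsAsFactors = FALSE),
        as.data.frame(scores))
    }
  }
  structure(
    list(subjects = subjects, series = series, confounds = confounds,
         clinical = do.call(rbind, clin_rows), graphs = graphs,
         true_edge_strength = truth,
         images = if (voxels) images, maps = maps, spec = spec),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic study: %d patients + %d controls x 2 sessions, T = %d, TR = %gs\n",
    x$spec$n_patients, x$spec$n_controls, x$spec$n_timepoints,
    x$spec$tr_seconds))
  cat(sprintf("Designated edge %s -> %s: deficit %.2f, training gain %.2f\n",
              x$spec$edge[1L], x$spec$edge[2L], x$spec$patient_edge_deficit,
              x$spec$training_edge_gain))
  invisible(x)
}

#' Write a synthetic study to disk as plain-text files
#'
#' Per subject-session TSV time series and confound tables, one clinical
#' TSV, and a JSON ground-truth file (graphs, designated edge, clinical link
#' parameters).
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(study$series))
    for (sess in names(study$series[[id]])) {
      write_timeseries_tsv(study$series[[id]][[sess]],
                           file.path(dir, sprintf("%s_%s_timeseries.tsv",
                                                  id, sess)))
      utils::write.table(study$confounds[[id]][[sess]],
                         file.path(dir, sprintf("%s_%s_confounds.tsv",
                                                id, sess)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  utils::write.table(study$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    edge = study$spec$edge,
    patient_edge_deficit = study$spec$patient_edge_deficit,
    training_edge_gain = study$spec$training_edge_gain,
    clinical_link = study$spec$clinical_link,
    base_coeffs = study$spec$base_graph$coeffs,
    noise_vars = study$spec$base_graph$noise_vars,
    true_edge_strength = study$true_edge_strength)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
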