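#' Derive a per-stage seed from a global seed
#'
#' Counter-based fan-out keeping every derived seed a valid 32-bit integer,
#' so one global seed reproduces an entire multi-stage run without seed
#' collisions between stages.
#'
#' @param base global integer seed.
#' @param index stage counter (>= 0).
#' @return derived integer seed.
#' @export
derive_seed <- function(base, index) {
  as.integer((as.numeric(base) * 2654435761 + as.numeric(index) * 40503) %%
               2147483647)
}

#' Pipeline configuration
#'
#' All stage parameters with the field-standard defaults: band 0.01-0.1 Hz,
#' FD threshold 0.5 mm, DVARS threshold 1.5, cluster-forming p 0.005,
#' cluster FWE 0.05, FDR 0.05, correlation threshold 0.05, TR 2 s.
#'
#' @param seed global seed fanned out to the stages via [derive_seed()].
#' @param study a [study_spec()] for the synthesis stage.
#' @param band frequency band (Hz) for filtering and GPDC averaging.
#' @param fd_thresh,dvars_thresh motion-outlier thresholds.
#' @param n_compcor CompCor components regressed out (0 disables).
#' @param p_max maximal VAR order for AIC.
#' @param fdr_q FDR level for the edge tests.
#' @param p_form,p_fwe cluster-forming and cluster-level thresholds.
#' @param alpha per-edge surrogate detection level.
#' @param n_surrogates surrogates per subject (0 disables edge detection).
#' @param run_ica run the voxel/ICA branch (slower).
#' @param out_dir output directory, or `NULL` for in-memory results only.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, study = study_spec(seed = seed),
                            band = c(0.01, 0.1), fd_thresh = 0.5,
                            dvars_thresh = 1.5, n_compcor = 0L,
                            p_max = 6L, fdr_q = 0.05, p_form = 0.005,
                            p_fwe = 0.05, alpha = 0.05, n_surrogates = 0L,
                            run_ica = FALSE, out_dir = NULL) {
  nyq <- 1 / (2 * study$tr_seconds)
  if (band[2L] >= nyq)
    stop(sprintf("infeasible band: %.3g Hz is not below Nyquist %.3g Hz",
                 band[2L], nyq))
  stopifnot(band[1L] > 0, band[1L] < band[2L], fd_thresh > 0,
            dvars_thresh > 0, p_max >= 1L, fdr_q > 0, fdr_q < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes synthesis, temporal preprocessing (band-pass + optional CompCor
#' regression + motion censoring), optionally the group-ICA voxel branch,
#' the causal core (AIC order selection, MVAR, band-averaged GPDC), the
#' edge-wise group statistics (baseline between-group test, paired tests
#' per group, one-sample tests), optional surrogate edge detection with
#' frequency maps, and the clinical correlations. When `out_dir` is set,
#' all tabular results and a provenance record (config, seeds, per-stage
#' parameter decisions) are written there.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `pipeline_result`: `study`, `table`
#'   (the [study_table()]), `order`, `tests` (list: `between_baseline`,
#'   `between_after`, `paired_patient`, `paired_control`,
#'   `one_sample_baseline`), `correlations` (RP/BP levels + differences),
#'   `detection` (if surrogates requested), `ica` (if `run_ica`),
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  study <- generate_study(config$study, voxels = config$run_ica)

  # preprocessing: censor masks + band-pass (+ optional CompCor regression);
  # the raw (unfiltered) series are kept for surrogate detection, whose
  # phase-randomization null requires stationary input
  raw_series <- study$series
  for (id in names(study$series))
    for (sess in names(study$series[[id]])) {
      x <- study$series[[id]][[sess]]
      conf <- study$confounds[[id]][[sess]]
      if (config$n_compcor > 0L) {
        noise <- as.matrix(conf[, grep("^noise_voxel_", names(conf)),
                                drop = FALSE])
        x <- regress_confounds(x, compcor_components(noise,
                                                     config$n_compcor))
      }
      mask <- censor_outliers(conf, config$fd_thresh, config$dvars_thresh)
      raw <- x
      attr(raw, "censor_mask") <- mask
      raw_series[[id]][[sess]] <- raw
      x <- bandpass(x, config$band[1L], config$band[2L],
                    tr_seconds = config$study$tr_seconds)
      attr(x, "censor_mask") <- mask
      study$series[[id]][[sess]] <- x
    }

  ica <- NULL
  if (config$run_ica) {
    imgs <- unlist(study$images, recursive = FALSE)
    ica <- fit_group_ica(imgs, n_components = study$spec$base_graph$n_nodes,
                         seed = derive_seed(config$seed, 1L))
  }

  table <- compute_edge_tables(study, band = config$band,
                               p_max = config$p_max, filter = FALSE)
  tests <- list(
    between_baseline = independent_t_edges(table, "before", q = config$fdr_q),
    between_after = independent_t_edges(table, "after", q = config$fdr_q),
    paired_patient = paired_t_edges(table, "patient", q = config$fdr_q),
    paired_control = paired_t_edges(table, "control", q = config$fdr_q),
    one_sample_baseline = one_sample_edges(table, session = "before",
                                           q = config$fdr_q))

  edge <- config$study$edge
  correlations <- list(
    RP_levels = edge_score_correlation(table, edge, "RP", session = "after"),
    BP_levels = edge_score_correlation(table, edge, "BP", session = "after"),
    RP_differences = edge_score_correlation(table, edge, "RP",
                                            mode = "differences"),
    BP_differences = edge_score_correlation(table, edge, "BP",
                                            mode = "differences"))

  detection <- NULL
  if (config$n_surrogates > 0L) {
    dets <- list()
    i <- 0L
    for (id in names(study$series)) {
      i <- i + 1L
      dets[[id]] <- detect_edges_surrogate(
        raw_series[[id]][["before"]], config$n_surrogates,
        config$alpha, seed = derive_seed(config$seed, 100L + i),
        order = attr(table, "order"), band = config$band)$detected
    }
    detection <- list(per_subject = dets,
                      frequency = edge_frequency(dets))
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("gpdcnet")),
    seed = config$seed,
    band_hz = config$band,
    fd_thresh_mm = config$fd_thresh, dvars_thresh = config$dvars_thresh,
    var_order = attr(table, "order"), p_max = config$p_max,
    fdr_q = config$fdr_q,
    aic_variant = "logdet(Sigma_ML) + 2*p*N^2/T_eff",
    filter = "Butterworth order 4, zero-phase (filtfilt)",
    fdr_family = "off-diagonal directed edges within each contrast",
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  result <- structure(
    list(study = study, table = table, order = attr(table, "order"),
         tests = tests, correlations = correlations,
         detection = detection, ica = ica, provenance = provenance),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config)
  result
}

write_pipeline_result <- function(result, config) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$tests))
    write_edge_test_tsv(result$tests[[nm]],
                        file.path(dir, paste0("test_", nm, ".tsv")))
  for (id in names(result$table$edges))
    for (sess in names(result$table$edges[[id]]))
      write_edge_tsv(result$table$edges[[id]][[sess]],
                     file.path(dir, sprintf("edges_%s_%s.tsv", id, sess)))
  if (!is.null(result$detection))
    write_edge_tsv(result$detection$frequency,
                   file.path(dir, "edge_frequency.tsv"))
  cors <- lapply(result$correlations, function(cc)
    cc[c("r", "r_squared", "p", "n", "slope", "intercept")])
  jsonlite::write_json(cors, file.path(dir, "correlations.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  prov <- result$provenance
  prov$elapsed_seconds <- NULL   # keep provenance byte-reproducible
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: VAR order %d, band %.3g-%.3g Hz\n",
              x$order, x$provenance$band_hz[1L], x$provenance$band_hz[2L]))
  edge <- x$study$spec$edge
  bt <- x$tests$between_baseline
  row <- bt[bt$source == edge[1L] & bt$target == edge[2L], ]
  cat(sprintf(
    "Designated edge %s -> %s at baseline: t = %.2f, q = %.4f (%s)\n",
    edge[1L], edge[2L], row$t, row$q,
    if (row$significant) "flagged" else "not flagged"))
  for (nm in names(x$tests)) {
    tst <- x$tests[[nm]]
    cat(sprintf("  %-20s %d/%d edges flagged at FDR %.2f\n", nm,
                sum(tst$significant), nrow(tst), attr(tst, "q_level")))
  }
  cat("Correlations (patients):\n")
  for (nm in names(x$correlations)) {
    cc <- x$correlations[[nm]]
    cat(sprintf("  %-15s r = %+.3f (r^2 = %.3f, p = %.4f, n = %d)\n",
                nm, cc$r, cc$r_squared, cc$p, cc$n))
  }
  invisible(x)
}
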