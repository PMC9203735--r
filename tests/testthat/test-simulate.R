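test_that("simulate_var matches stationary theory and rejects bad graphs", {
  # white noise: no temporal structure
  g0 <- causal_graph(matrix(0, 3, 3), noise_vars = 1)
  x <- simulate_var(g0, 5000, seed = 1)
  for (j in 1:3) {
    r1 <- cor(x[-1, j], x[-nrow(x), j])
    expect_lt(abs(r1), 0.05)
  }
  # AR(1) variance: sigma^2 / (1 - a^2)
  g1 <- causal_graph(matrix(0.9, 1, 1), noise_vars = 1)
  v <- var(simulate_var(g1, 10000, seed = 2)[, 1])
  expect_lt(abs(v - 1 / (1 - 0.81)) / (1 / (1 - 0.81)), 0.1)
  # random walk is rejected with the spectral radius in the message
  expect_error(simulate_var(causal_graph(matrix(1, 1, 1)), 100),
               "spectral radius")
  expect_error(causal_graph(matrix(0.5, 1, 1), noise_vars = 0), "positive")
  expect_error(causal_graph(matrix(Inf, 1, 1)), "finite")
})

test_that("simulate_var is deterministic and short series are refused", {
  g <- default_study_graph()
  expect_identical(simulate_var(g, 100, seed = 5),
                   simulate_var(g, 100, seed = 5))
  expect_error(simulate_var(g, 10), "exceed")
})

test_that("generating recursion leaves residuals with the planted variances", {
  g <- random_stable_graph(4, 2, seed = 11)
  x <- simulate_var(g, 2000, seed = 12)
  t_n <- nrow(x)
  pred <- matrix(0, t_n - 2, 4)
  for (k in 1:2)
    pred <- pred + x[(3 - k):(t_n - k), ] %*% t(g$coeffs[[k]])
  resid <- x[3:t_n, ] - pred
  expect_true(all(abs(apply(resid, 2, var) - g$noise_vars) /
                    g$noise_vars < 0.15))
})

test_that("HRF convolution behaves as a linear causal filter", {
  tr <- 2
  h <- hrf_kernel(tr)
  # impulse reproduces the kernel
  imp <- matrix(0, 60, 1)
  imp[1, 1] <- 1
  attr(imp, "sampling_interval") <- tr
  out <- convolve_hrf(imp)
  expect_equal(out[seq_along(h), 1], h, tolerance = 1e-10)
  # zeros map to zeros
  z <- matrix(0, 50, 2)
  expect_true(all(convolve_hrf(z, tr) == 0))
  # white noise becomes smooth
  set.seed(3)
  w <- matrix(rnorm(500), ncol = 1)
  cw <- convolve_hrf(w, tr)
  expect_gt(cor(cw[-1, 1], cw[-500, 1]), 0.5)
})

test_that("render_voxels plants recoverable spatial structure", {
  maps <- blob_maps(2, dims = c(8L, 8L, 8L))
  g <- random_stable_graph(2, 1, seed = 21)
  ts <- simulate_var(g, 100, seed = 22)
  # noiseless single node: every in-blob voxel is a scalar multiple
  img <- render_voxels(maps[1, , drop = FALSE], ts[, 1, drop = FALSE],
                       noise_sd = 0)
  vox <- which(maps[1, ] > 0.5)
  for (vx in vox[1:5])
    expect_equal(cor(img[, vx], ts[, 1]), 1, tolerance = 1e-10)
  # inter-blob voxel correlation tracks the node-series correlation
  img2 <- render_voxels(maps, ts, noise_sd = 0)
  core1 <- which(maps[1, ] > 0.9 & maps[2, ] < 0.05)[1]
  core2 <- which(maps[2, ] > 0.9 & maps[1, ] < 0.05)[1]
  expect_lt(abs(cor(img2[, core1], img2[, core2]) - cor(ts[, 1], ts[, 2])),
            0.1)
  # degenerate inputs
  expect_error(render_voxels(maps, ts[, 1, drop = FALSE]), "mismatch")
  img3 <- render_voxels(matrix(0, 2, 512), ts, noise_sd = 1, seed = 1)
  expect_lt(abs(mean(img3)), 0.02)
})

test_that("generate_study applies the deficit/gain arithmetic to ground truth", {
  base <- default_study_graph()
  spec <- study_spec(n_patients = 2, n_controls = 2, n_timepoints = 60,
                     patient_edge_deficit = 0.3, training_edge_gain = 3,
                     subject_edge_sd = 0, seed = 9)
  st <- generate_study(spec)
  a_base <- base$coeffs[[1]]["DMN", "SMN"]
  expect_equal(st$graphs$S01$before$coeffs[[1]]["DMN", "SMN"], 0.3 * a_base)
  expect_equal(st$graphs$S01$after$coeffs[[1]]["DMN", "SMN"], 0.9 * a_base)
  expect_equal(st$graphs$S03$before$coeffs[[1]]["DMN", "SMN"], a_base)
  expect_equal(st$graphs$S03$after$coeffs[[1]]["DMN", "SMN"], a_base)
  # neutral spec: every graph equals the base graph
  neutral <- study_spec(n_patients = 2, n_controls = 2, n_timepoints = 60,
                        patient_edge_deficit = 1, training_edge_gain = 1,
                        subject_edge_sd = 0, seed = 9)
  stn <- generate_study(neutral)
  for (id in names(stn$graphs))
    for (sess in c("before", "after"))
      expect_equal(stn$graphs[[id]][[sess]]$coeffs, base$coeffs)
})

test_that("study generation is reproducible and clinically coherent", {
  spec <- study_spec(n_patients = 3, n_controls = 3, n_timepoints = 80,
                     clinical_link = list(
                       RP = list(intercept = 30, slope = 150, noise_sd = 0)),
                     seed = 4)
  s1 <- generate_study(spec)
  s2 <- generate_study(spec)
  expect_identical(s1$series, s2$series)
  expect_identical(s1$clinical, s2$clinical)
  # noiseless clinical link: score is an exact line in the true strength
  truth <- unlist(s1$true_edge_strength)
  key <- paste(s1$clinical$subject_id, s1$clinical$session, sep = ".")
  expect_equal(cor(s1$clinical$RP, truth[key]), 1, tolerance = 1e-12)
  # every generated graph passes the stability check
  for (id in names(s1$graphs))
    for (sess in c("before", "after"))
      expect_lt(spectral_radius(s1$graphs[[id]][[sess]]), 1)
})

test_that("generated confound tables plant the requested outlier fraction", {
  set.seed(2)
  spec <- study_spec(n_patients = 2, n_controls = 2, n_timepoints = 400,
                     outlier_frac = 0.05, seed = 3)
  st <- generate_study(spec)
  fr <- vapply(names(st$confounds), function(id)
    mean(!censor_outliers(st$confounds[[id]]$before)$keep), numeric(1))
  expect_true(all(abs(fr - 0.05) < 0.02))
})
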