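test_that("MDL counts planted sources and returns ~0 for noise", {
  set.seed(71)
  src <- matrix(rnorm(3 * 2000), 2000, 3)
  mix <- matrix(rnorm(60), 3, 20)
  dat <- src %*% mix + matrix(rnorm(2000 * 20, sd = 0.05), 2000)
  expect_equal(as.integer(estimate_ncomp_mdl(dat)), 3L)
  noise <- matrix(rnorm(2000 * 10), 2000, 10)
  expect_lte(as.integer(estimate_ncomp_mdl(noise)), 1L)
  # exact low rank with zero noise: flooring kicks in, rank recovered
  lowrank <- src %*% mix
  expect_warning(q <- estimate_ncomp_mdl(lowrank), "flooring")
  expect_equal(as.integer(q), 3L)
  expect_error(estimate_ncomp_mdl(matrix(1, 5, 10)), "observations")
})

test_that("goodness of fit is the in-minus-out template mean", {
  tpl <- c(rep(TRUE, 20), rep(FALSE, 80))
  expect_equal(goodness_of_fit(as.numeric(tpl), tpl), 1)
  expect_equal(goodness_of_fit(rep(0.7, 100), tpl), 0)
  # two-mean oracle on a random map
  set.seed(72)
  map <- rnorm(100)
  expect_equal(goodness_of_fit(map, tpl),
               mean(map[1:20]) - mean(map[21:100]))
  expect_error(goodness_of_fit(map, rep(TRUE, 100)), "template")
  expect_error(goodness_of_fit(map, rep(FALSE, 100)), "template")
})

make_planted_decomposition <- function(maps) {
  structure(list(n_components = nrow(maps), group_maps = maps,
                 timecourses = list(), subject_maps = list(),
                 stability = rep(1, nrow(maps)), best_restart = 1L,
                 converged = TRUE, dims = attr(maps, "dims")),
            class = "ica_decomposition")
}

test_that("network assignment recovers identity, permutation, and noise", {
  maps <- blob_maps(4, dims = c(8L, 8L, 8L))
  z <- t(scale(t(maps)))   # z-scored rows, as fit_group_ica produces
  templates <- lapply(1:4, function(i) maps[i, ] > 0.4)
  names(templates) <- c("DMN", "SMN", "VN", "SN")
  # identity
  asg <- assign_networks(make_planted_decomposition(z), templates)
  expect_equal(asg$component, 1:4)
  expect_true(all(asg$score > 0))
  # permuted components are traced back
  perm <- c(3, 1, 4, 2)
  asg2 <- assign_networks(make_planted_decomposition(z[perm, ]), templates)
  expect_equal(asg2$component, order(perm))
  # an extra pure-noise component receives no label
  set.seed(73)
  withnoise <- rbind(z, rnorm(ncol(z)))
  asg3 <- assign_networks(make_planted_decomposition(withnoise), templates)
  expect_false(5L %in% asg3$component)
  expect_error(assign_networks(make_planted_decomposition(z[1:2, ]),
                               templates), "fewer components")
})

test_that("group ICA recovers planted sources and is deterministic", {
  spec <- study_spec(n_patients = 2, n_controls = 2, n_timepoints = 120,
                     seed = 74)
  st <- generate_study(spec, voxels = TRUE, voxel_noise_sd = 0.3,
                       voxel_dims = c(10L, 10L, 10L))
  imgs <- unlist(st$images, recursive = FALSE)
  dec <- fit_group_ica(imgs, n_components = 6, n_restarts = 3, seed = 75)
  mm <- gpdcnet:::match_components(dec$group_maps, st$maps)$abs_cor
  expect_true(all(mm >= 0.85))
  # byte-identical rerun under the same seed
  dec2 <- fit_group_ica(imgs, n_components = 6, n_restarts = 3, seed = 75)
  expect_identical(dec$group_maps, dec2$group_maps)
  expect_identical(dec$timecourses, dec2$timecourses)
  # dual-regression time courses track the planted node series
  tc_cor <- vapply(seq_along(imgs), function(i) {
    planted <- st$series[[ceiling(i / 2)]][[2 - i %% 2]]
    max(abs(cor(dec$timecourses[[i]], planted)))
  }, numeric(1))
  expect_true(all(tc_cor > 0.9))
})

test_that("single-source data yields one matching time course", {
  g <- causal_graph(matrix(0.5, 1, 1))
  ts <- simulate_var(g, 150, seed = 76)
  maps <- blob_maps(1, dims = c(8L, 8L, 8L))
  img <- render_voxels(maps, ts, noise_sd = 0.05, seed = 77)
  dec <- fit_group_ica(list(img), n_components = 1, n_restarts = 2,
                       seed = 78)
  expect_gt(abs(cor(dec$timecourses[[1]][, 1], ts[, 1])), 0.99)
})
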