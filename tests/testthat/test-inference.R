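# tiny study-table fixture with controllable edge values
toy_table <- function(edge_fun, n_pat = 5, n_ctl = 5, nodes = c("A", "B", "C"),
                      clinical = NULL) {
  n <- length(nodes)
  ids <- sprintf("S%02d", seq_len(n_pat + n_ctl))
  subjects <- data.frame(subject_id = ids,
                         group = rep(c("patient", "control"),
                                     c(n_pat, n_ctl)))
  edges <- lapply(seq_along(ids), function(s) {
    list(before = edge_fun(s, "before"), after = edge_fun(s, "after"))
  })
  names(edges) <- ids
  study_table(edges, subjects, clinical)
}

named_matrix <- function(vals, nodes) {
  m <- matrix(vals, length(nodes), length(nodes))
  dimnames(m) <- list(nodes, nodes)
  m
}

test_that("one-sample edge test matches the hand formula and degenerates", {
  nodes <- c("A", "B", "C")
  set.seed(91)
  vals <- lapply(1:10, function(s) named_matrix(runif(9, 0.2, 0.6), nodes))
  tab <- toy_table(function(s, sess) vals[[s]])
  res <- one_sample_edges(tab, session = "before")
  # oracle at edge A -> B: mean/sd/sqrt(n)
  x <- vapply(1:10, function(s) vals[[s]]["B", "A"], numeric(1))
  r <- edge_row(res, "A", "B")
  expect_equal(r$t, mean(x) / (sd(x) / sqrt(10)), tolerance = 1e-12)
  expect_equal(r$mean, mean(x))
  # identical positive matrices across subjects: everything flagged
  const <- named_matrix(0.4, nodes)
  tab2 <- toy_table(function(s, sess) const)
  res2 <- suppressMessages(one_sample_edges(tab2))
  expect_true(all(res2$significant == (res2$p < 1)))
  expect_error(one_sample_edges(toy_table(function(s, sess) const,
                                          n_pat = 1, n_ctl = 1)),
               "3 subjects")
})

test_that("independent edge test is a pooled two-sample t with sign symmetry", {
  nodes <- c("A", "B")
  set.seed(92)
  pat_vals <- replicate(6, named_matrix(c(0, 0.1, 0.5, 0) + rnorm(4, sd = 0.05),
                                        nodes), simplify = FALSE)
  ctl_vals <- replicate(6, named_matrix(c(0, 0.4, 0.5, 0) + rnorm(4, sd = 0.05),
                                        nodes), simplify = FALSE)
  tab <- toy_table(function(s, sess)
    if (s <= 6) pat_vals[[s]] else ctl_vals[[s - 6]], n_pat = 6, n_ctl = 6)
  res <- independent_t_edges(tab, "before")
  r <- edge_row(res, "A", "B")
  # oracle: pooled-variance t
  xp <- vapply(1:6, function(s) pat_vals[[s]]["B", "A"], numeric(1))
  xc <- vapply(1:6, function(s) ctl_vals[[s]]["B", "A"], numeric(1))
  sp2 <- (5 * var(xp) + 5 * var(xc)) / 10
  expect_equal(r$t, (mean(xp) - mean(xc)) / sqrt(sp2 * (2 / 6)),
               tolerance = 1e-12)
  expect_lt(r$t, 0)   # patients lower
  # swapping the group labels flips every t
  tab_sw <- tab
  tab_sw$subjects$group <- rev(tab$subjects$group)
  res_sw <- independent_t_edges(tab_sw, "before")
  expect_equal(res_sw$t, -res$t, tolerance = 1e-12)
})

test_that("paired edge test equals the one-sample test of differences", {
  nodes <- c("A", "B", "C")
  set.seed(93)
  gain <- named_matrix(0, nodes)
  gain["B", "A"] <- 0.25
  base_vals <- replicate(10, named_matrix(runif(9, 0.2, 0.5), nodes),
                         simplify = FALSE)
  noise <- replicate(10, named_matrix(rnorm(9, sd = 0.03), nodes),
                     simplify = FALSE)
  tab <- toy_table(function(s, sess)
    if (sess == "before") base_vals[[s]]
    else base_vals[[s]] + gain + noise[[s]],
    n_pat = 8, n_ctl = 2)
  res <- paired_t_edges(tab, "patient")
  r <- edge_row(res, "A", "B")
  expect_true(r$significant)
  expect_gt(r$t, 0)
  # identity: paired t == one-sample t of the differences
  d <- vapply(1:8, function(s) (gain + noise[[s]])["B", "A"], numeric(1))
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(8)), tolerance = 1e-12)
  # after == before: all zero, nothing flagged
  tab0 <- toy_table(function(s, sess) base_vals[[s]], n_pat = 8, n_ctl = 2)
  res0 <- suppressMessages(paired_t_edges(tab0, "patient"))
  expect_true(all(res0$t == 0))
  expect_true(all(!res0$significant))
})

test_that("BH step-up matches the hand computation and controls FDR", {
  adj <- bh_fdr(c(0.01, 0.02, 0.03, 0.5))
  expect_equal(adj$qvals, c(0.04, 0.04, 0.04, 0.5), tolerance = 1e-12)
  expect_equal(adj$flags, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(!bh_fdr(rep(1, 10))$flags))
  # q >= p always
  set.seed(94)
  p <- runif(50)
  expect_true(all(bh_fdr(p)$qvals >= p))
  # null calibration: P(any rejection) <= ~alpha under independence
  any_rej <- vapply(1:400, function(s) {
    any(bh_fdr(runif(30))$flags)
  }, logical(1))
  expect_lte(mean(any_rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
})

test_that("edge frequency is the subject-wise detection mean", {
  det1 <- matrix(c(NA, 1, 0, NA), 2, 2)
  det0 <- matrix(c(NA, 0, 0, NA), 2, 2)
  freq <- edge_frequency(c(replicate(10, det1, simplify = FALSE),
                           replicate(10, det0, simplify = FALSE)))
  expect_equal(freq[2, 1], 0.5)
  expect_equal(freq[1, 2], 0)
  expect_equal(edge_frequency(list(det1))[2, 1], 1)
  expect_error(edge_frequency(list(det1, matrix(0, 3, 3))), "inconsistent")
})

test_that("clinical correlation is Pearson with exact p and modes", {
  nodes <- c("A", "B")
  # noiseless linear link: r exactly 1 in both modes
  strength <- seq(0.2, 0.6, length.out = 5)
  tab <- toy_table(function(s, sess) {
    m <- named_matrix(0, nodes)
    m["B", "A"] <- strength[s] + 0.1 * (sess == "after")
    m
  }, n_pat = 5, n_ctl = 0,
  clinical = data.frame(
    subject_id = rep(sprintf("S%02d", 1:5), each = 2),
    session = rep(c("before", "after"), 5),
    RP = 30 + 150 * rep(strength, each = 2) +
      rep(c(0, 15), 5)))
  lv <- edge_score_correlation(tab, c("A", "B"), "RP", session = "after")
  expect_equal(lv$r, 1, tolerance = 1e-12)
  expect_equal(lv$r_squared, 1, tolerance = 1e-12)
  # covariance-formula oracle on a small fixed table
  set.seed(95)
  xs <- runif(5); ys <- 2 * xs + rnorm(5)
  tab2 <- toy_table(function(s, sess) {
    m <- named_matrix(0, nodes)
    m["B", "A"] <- xs[s]
    m
  }, n_pat = 5, n_ctl = 0,
  clinical = data.frame(subject_id = rep(sprintf("S%02d", 1:5), each = 2),
                        session = rep(c("before", "after"), 5),
                        BP = rep(ys, each = 2)))
  cv <- edge_score_correlation(tab2, c("A", "B"), "BP", session = "before")
  r_oracle <- sum((xs - mean(xs)) * (ys - mean(ys))) /
    sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
  expect_equal(cv$r, r_oracle, tolerance = 1e-12)
  t_oracle <- r_oracle * sqrt(3) / sqrt(1 - r_oracle^2)
  expect_equal(cv$p, 2 * pt(-abs(t_oracle), df = 3), tolerance = 1e-12)
  # constant variable is refused
  tabc <- toy_table(function(s, sess) named_matrix(0.3, nodes),
                    n_pat = 5, n_ctl = 0,
                    clinical = tab2$clinical)
  expect_error(edge_score_correlation(tabc, c("A", "B"), "BP"),
               "constant")
})
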