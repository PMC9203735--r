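make_ts <- function(x, tr = 2) {
  m <- as.matrix(x)
  attr(m, "sampling_interval") <- tr
  m
}

# FFT amplitude of a single frequency component
fft_amp <- function(x, f_hz, tr) {
  t_n <- length(x)
  2 * Mod(fft(x))[round(f_hz * t_n * tr) + 1] / t_n
}

test_that("bandpass passes the band and kills what lies outside it", {
  tr <- 2
  tt <- (0:799) * tr
  inband <- make_ts(sin(2 * pi * 0.05 * tt))
  out <- bandpass(inband)
  expect_gt(fft_amp(out[, 1], 0.05, tr), 0.9)
  stopband <- make_ts(sin(2 * pi * 0.2 * tt))
  expect_lt(fft_amp(bandpass(stopband)[, 1], 0.2, tr), 0.1)
  # DC is removed entirely
  expect_equal(max(abs(bandpass(make_ts(rep(5, 400))))), 0)
  expect_lt(abs(mean(out)), 1e-10)
})

test_that("bandpass refuses infeasible bands, naming the Nyquist limit", {
  x <- make_ts(rnorm(100))
  expect_error(bandpass(x, 0.01, 0.3), "Nyquist")
  expect_error(bandpass(x, 0.2, 0.1), "low_hz")
  expect_error(bandpass(matrix(rnorm(100), ncol = 1)), "sampling interval")
})

test_that("bandpass is idempotent on band-limited content", {
  tr <- 2
  t_n <- 600
  tt <- (0:(t_n - 1)) * tr
  raw <- sin(2 * pi * 0.03 * tt) + 0.6 * sin(2 * pi * 0.07 * tt + 1)
  # cosine-tapered ends keep the probe free of boundary discontinuities,
  # isolating the filter response from reflection-padding kinks
  taper <- rep(1, t_n)
  k <- 60
  taper[1:k] <- 0.5 * (1 - cos(pi * (0:(k - 1)) / k))
  taper[t_n:(t_n - k + 1)] <- taper[1:k]
  x <- make_ts(raw * taper)
  b1 <- bandpass(x)
  b2 <- bandpass(b1)
  expect_lt(max(abs(b2 - b1)), 0.05 * sd(b1))
})

test_that("compcor recovers a planted common component", {
  set.seed(10)
  t_n <- 200
  common <- sin(2 * pi * 0.04 * (0:(t_n - 1)) * 2)
  noise_series <- sapply(1:40, function(i)
    common * runif(1, 0.5, 2) + rnorm(t_n, sd = 0.02))
  pcs <- compcor_components(noise_series, k = 3)
  expect_gt(abs(cor(pcs[, 1], common)), 0.99)
  # unit variance, mutual orthogonality
  expect_equal(apply(pcs, 2, sd), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(max(abs(cor(pcs)[upper.tri(diag(3))])), 1e-10)
  # edge cases
  expect_equal(ncol(compcor_components(noise_series, k = 0)), 0)
  expect_error(compcor_components(noise_series, k = 60), "below")
  expect_error(compcor_components(matrix(1, 50, 5), k = 2), "constant")
})

test_that("confound regression leaves residuals orthogonal to regressors", {
  set.seed(11)
  t_n <- 150
  reg <- cbind(rnorm(t_n), rnorm(t_n))
  noise <- rnorm(t_n)
  ts <- make_ts(cbind(reg[, 1],                    # pure confound
                      reg[, 1] + noise))           # confound + signal
  res <- regress_confounds(ts, reg)
  expect_lt(max(abs(res[, 1])), 1e-10)
  expect_gt(cor(res[, 2], noise), 0.99)
  for (j in 1:2)
    expect_lt(abs(sum(res[, 2] * reg[, j])) /
                sqrt(sum(res[, 2]^2) * sum(reg[, j]^2)), 1e-8)
  # no regressors: demeaning only
  plain <- regress_confounds(ts, NULL)
  expect_equal(plain, scale(ts, scale = FALSE), ignore_attr = TRUE)
  # collinear columns are dropped with a warning, not an error
  expect_warning(regress_confounds(ts, cbind(reg, reg[, 1])), "collinear")
})

test_that("confound regression never inflates channel variance", {
  set.seed(12)
  for (rep in 1:5) {
    ts <- make_ts(matrix(rnorm(100 * 3), 100, 3))
    reg <- matrix(rnorm(100 * 4), 100, 4)
    res <- regress_confounds(ts, reg)
    expect_true(all(apply(res, 2, var) <= apply(ts, 2, var) + 1e-12))
  }
})

test_that("outlier censoring follows the strict FD/DVARS threshold rule", {
  conf <- data.frame(framewise_displacement = c(0.1, 0.6, 0.1),
                     std_dvars = c(1.0, 1.0, 1.0))
  m <- censor_outliers(conf)
  expect_equal(which(!m$keep), 2L)
  expect_equal(m$reason[2], "FD")
  # both rules firing is recorded as such
  conf2 <- data.frame(framewise_displacement = c(0.1, 0.7),
                      std_dvars = c(1.9, 1.8))
  expect_equal(censor_outliers(conf2)$reason, c("DVARS", "FD+DVARS"))
  # boundary: exactly at threshold is retained
  conf3 <- data.frame(framewise_displacement = 0.5, std_dvars = 1.5)
  expect_true(all(censor_outliers(conf3)$keep))
  # below both thresholds: nothing flagged
  expect_true(all(censor_outliers(conf)$keep[-2]))
})

test_that("raising censoring thresholds never flags more frames", {
  set.seed(13)
  conf <- data.frame(framewise_displacement = abs(rnorm(300, 0.3, 0.2)),
                     std_dvars = abs(rnorm(300, 1.2, 0.4)))
  base <- sum(!censor_outliers(conf, 0.5, 1.5)$keep)
  for (ft in c(0.6, 0.8)) for (dt in c(1.6, 2.0))
    expect_lte(sum(!censor_outliers(conf, ft, dt)$keep), base)
})
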