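test_that("Gaussian smoothing preserves constants, mass, and linearity", {
  x <- rep(3.7, 500)
  expect_equal(gaussian_smooth(x, 10, rate = 1000), x)
  ## unit impulse: output is the kernel, summing to 1
  imp <- c(rep(0, 250), 1, rep(0, 250))
  k <- gaussian_smooth(imp, 10, rate = 1000)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_equal(which.max(k), 251)
  ## linearity to machine precision
  set.seed(21)
  a <- rnorm(400); b <- rnorm(400)
  expect_equal(gaussian_smooth(2 * a - 3 * b, 10, rate = 1000),
               2 * gaussian_smooth(a, 10, rate = 1000) -
                 3 * gaussian_smooth(b, 10, rate = 1000), tolerance = 1e-12)
  ## white-noise variance scales by the kernel's squared norm
  set.seed(22)
  w <- rnorm(2e5)
  sm <- gaussian_smooth(w, 10, rate = 1000)
  expect_equal(var(sm) / var(w), sum(k^2), tolerance = 0.05)
  expect_error(gaussian_smooth(a, -1, rate = 1000), "sigma")
})

test_that("EMG preprocessing has the specified band, gain, and normalization", {
  rate <- 2000
  t <- seq(0, 4, by = 1 / rate)
  ## frequency response oracle: 100 Hz passes (gain ~ 1), 5 Hz attenuated > 20 dB
  for (freq in c(5, 100)) {
    s <- sin(2 * pi * freq * t)
    y <- graspdyn:::butter_zerophase(s, n = 3, cutoff_hz = c(25, 250),
                                     rate = rate, type = "pass")
    gain <- sd(y[2000:6000]) / sd(s[2000:6000])
    if (freq == 100) expect_gt(gain, 0.95) else expect_lt(gain, 10^(-20 / 20))
  }
  ## a stationary signal normalizes to ~ 1 relative to its fixation epoch
  set.seed(23)
  raw <- continuous_signal(rnorm(8 * rate), rate, "uV", t0 = 0)
  env <- preprocess_emg(raw, fixation_windows = cbind(500, 1500))
  expect_equal(mean(env$samples[2000:14000]), 1, tolerance = 0.1)
  expect_equal(env$unit, "normalized")
  expect_error(preprocess_emg(continuous_signal(rnorm(100), 400), cbind(0, 50)),
               "rate")
})

test_that("median high-pass removes offsets and keeps transients", {
  expect_equal(median_highpass(rep(5, 1000), rate = 30000), rep(0, 1000))
  ## isolated 1-sample transient on a flat baseline survives >= 90%
  x <- rep(2, 1000); x[500] <- 12
  y <- median_highpass(x, rate = 30000)
  expect_gte(y[500], 0.9 * 10)
  ## 3.33 ms at 30 kHz: nearest odd window is 99 samples; interior matches
  ## a direct runmed subtraction
  set.seed(24)
  z <- rnorm(2000)
  y2 <- median_highpass(z, 3.33, rate = 30000)
  ref <- z - stats::runmed(z, 99, endrule = "keep")
  expect_equal(y2[100:1900], ref[100:1900], tolerance = 1e-12)
  expect_error(median_highpass(rnorm(10), 3.33, rate = 30000), "longer")
})

test_that("zero-phase filtering leaves the cross-correlation peak at lag 0", {
  set.seed(25)
  rate <- 2000
  x <- gaussian_smooth(rnorm(6000), 5, rate = rate)
  y <- graspdyn:::butter_zerophase(x, n = 3, cutoff_hz = c(25, 250),
                                   rate = rate, type = "pass")
  cc <- ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(abs(cc$acf))], 0)
  y2 <- lowpass_filter(x, 400, rate = rate)
  cc2 <- ccf(x, y2, lag.max = 20, plot = FALSE)
  expect_equal(cc2$lag[which.max(abs(cc2$acf))], 0)
})

test_that("PCA artifact cancellation removes common modes, keeps single channels", {
  set.seed(26)
  n <- 4000
  artifact <- sin(2 * pi * 60 * seq_len(n) / 30000) * 8
  signal <- rnorm(n) * 4
  X <- matrix(rnorm(n * 32, 0, 1), n, 32) + artifact   # common on all 32
  X[, 1] <- X[, 1] + signal                            # channel-specific
  res <- pca_artifact_cancel(X, 0.36)
  cleaned <- res$cleaned
  ## common waveform loading 1/sqrt(32) ~ 0.18 < 0.36: removed >= 20 dB
  resid <- sapply(1:32, function(j) coef(lm(cleaned[, j] ~ artifact))[2])
  expect_lt(max(abs(resid)), 0.1)
  ## single-channel signal loading ~ 1 > 0.36: preserved >= 95%
  b1 <- coef(lm(cleaned[, 1] ~ signal))[2]
  expect_gt(b1, 0.95)
  ## shape preserved and idempotent on the artifact subspace: the removed
  ## common-mode content stays removed and the kept signal stays intact
  expect_equal(dim(cleaned), dim(X))
  res2 <- pca_artifact_cancel(cleaned, 0.36)
  resid2 <- sapply(1:32, function(j) coef(lm(res2$cleaned[, j] ~ artifact))[2])
  expect_lt(max(abs(resid2)), 0.1)
  expect_gt(coef(lm(res2$cleaned[, 1] ~ signal))[2], 0.9)
  expect_error(pca_artifact_cancel(matrix(1:10, ncol = 1)), "channels")
})
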