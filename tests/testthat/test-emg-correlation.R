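test_that("shift scan recovers identity, lags, and stays low on noise", {
  set.seed(61)
  base <- gaussian_smooth(cumsum(rnorm(600)), 3, rate = 1000)
  a <- matrix(base[101:490], ncol = 1)
  ## a == b: argmax at 0 with R^2 = 1
  sc <- shift_scan(a, a)
  expect_equal(sc$shift[which.max(sc$r2)], 0)
  expect_equal(max(sc$r2), 1)
  expect_equal(range(sc$shift), c(-500, 500))
  ## constructed lag: b delayed by 50 ms (5 bins) -> chosen shift +50
  b <- matrix(base[101:490 - 5], ncol = 1)
  sc2 <- shift_scan(a, b)
  expect_equal(sc2$shift[which.max(sc2$r2)], 50)
  expect_gt(max(sc2$r2), 0.99)
  ## white-noise pair: max R^2 stays small at length 390
  wn <- shift_scan(matrix(rnorm(390)), matrix(rnorm(390)))
  expect_lt(max(wn$r2), 0.1)
  expect_error(shift_scan(matrix(rnorm(390)), matrix(0, 390)), "zero-variance")
})

test_that("R^2 is symmetric and the shift sign flips under swap", {
  set.seed(62)
  base <- gaussian_smooth(cumsum(rnorm(700)), 3, rate = 1000)
  a <- matrix(base[151:540], ncol = 1)
  b <- matrix(base[151:540 - 7] + rnorm(390, 0, 0.5), ncol = 1)
  s_ab <- shift_scan(a, b)
  s_ba <- shift_scan(b, a)
  expect_equal(s_ab$r2[s_ab$shift == 30], s_ba$r2[s_ba$shift == -30],
               tolerance = 1e-10)
  expect_equal(s_ab$shift[which.max(s_ab$r2)],
               -s_ba$shift[which.max(s_ba$r2)])
})

test_that("component correlation picks one shift and matches planted lags", {
  set.seed(63)
  ls <- latent_spec(n_units = 30)
  x <- latent_rate_tensor(ls)
  m <- dpca(x)
  ## EMG marginalizations manufactured from the model's own components:
  ## identical signals -> shift 0 and R^2 = 1 on the largest components
  emg <- array(0, dim = c(1, 3, 2, 390))
  k_ci <- which(m$marg == "condition_independent")[1]
  k_f <- which(m$marg == "force")[1]
  for (f in 1:3) for (g in 1:2)
    emg[1, f, g, ] <- m$scores[k_ci, f, g, ] + m$scores[k_f, f, g, ]
  res <- correlate_components(marginalize(emg), m)
  expect_equal(res$shift, 0)
  expect_equal(res$r2["condition_independent", 1], 1, tolerance = 1e-6)
  expect_equal(res$r2["force", 1], 1, tolerance = 1e-6)
  ## delayed EMG: lag recovered (neural leads muscle by 50 ms)
  emg_lag <- emg
  for (f in 1:3) for (g in 1:2) {
    v <- emg[1, f, g, ]
    emg_lag[1, f, g, ] <- c(rep(v[1], 5), v[1:385])
  }
  res_lag <- correlate_components(marginalize(emg_lag), m)
  expect_equal(res_lag$shift, 50, tolerance = 10)
  ## reference component switchable to the second largest
  spec2 <- shift_spec(ref_component = 2)
  k_ci2 <- which(m$marg == "condition_independent")[2]
  if (!is.na(k_ci2)) {
    res2 <- correlate_components(marginalize(emg), m, spec2)
    expect_s3_class(res2, "emg_correlation")
  }
})

test_that("planted lags are recovered within one bin at high SNR", {
  set.seed(64)
  hits <- 0; total <- 0
  for (lag_bins in c(-10, -4, 0, 4, 10)) {
    for (rep in 1:4) {
      ## dPC-like smoothness: 10-ms bins carrying 40-ms-smoothed noise
      base <- gaussian_smooth(rnorm(700), 40, rate = 100)
      idx <- 151:540
      a <- base[idx]
      b <- base[idx - lag_bins]
      b <- b + rnorm(390, 0, sd(b) / sqrt(10))   # SNR 10
      sc <- shift_scan(matrix(a), matrix(b), shift_spec(range_ms = 150))
      got <- sc$shift[which.max(sc$r2)]
      hits <- hits + (abs(got - lag_bins * 10) <= 10)
      total <- total + 1
    }
  }
  expect_gte(hits / total, 0.95)
})
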