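test_that("marginalization terms are centered and reconstruct the tensor", {
  set.seed(51)
  x <- array(rnorm(10 * 3 * 2 * 40), dim = c(10, 3, 2, 40))
  mg <- marginalize(x)
  recon <- Reduce(`+`, mg$terms)
  expect_lt(sum((recon - x)^2) / sum(x^2), 1e-20)
  ## each term averages to zero over every centered index
  expect_lt(max(abs(apply(mg$terms$t, c(1, 2, 3), mean))), 1e-12)
  expect_lt(max(abs(apply(mg$terms$tf, c(1, 2), mean))), 1e-12)
  expect_lt(max(abs(apply(mg$terms$tf, c(1, 3), mean))), 1e-12)
  ## balanced-design additivity of the combined shares
  expect_equal(sum(mg$shares), 1, tolerance = 1e-12)
  ## constant tensor: everything in the grand mean
  xc <- array(4.2, dim = c(3, 3, 2, 10))
  mgc <- marginalize(xc)
  expect_equal(mgc$terms$grand[1, 1, 1, 1], 4.2)
  expect_lt(sum(vapply(mgc$combined, function(m) sum(m^2), 0)), 1e-20)
  ## force-only tensor: grip and interaction marginalizations identically 0
  xf <- array(0, dim = c(4, 3, 2, 20))
  prof <- sin(seq(0, 3, length.out = 20))
  for (f in 1:3) xf[, f, , ] <- c(-1, 0, 1)[f] * rep(prof, each = 4 * 2)
  mgf <- marginalize(xf)
  expect_lt(sum(mgf$combined$grip^2) + sum(mgf$combined$interaction^2), 1e-20)
})

test_that("dPCA recovers planted structure and respects the PCA bound", {
  set.seed(52)
  ls <- latent_spec(n_units = 40)
  x <- latent_rate_tensor(ls)
  m <- dpca(x)
  ## noiseless single-latent marginalizations: one dominant component each
  for (mm in unique(m$marg))
    expect_gt(max(m$ev[m$marg == mm]) / m$marg_shares[[mm]], 0.99)
  expect_equal(unname(m$marg_shares), unname(ls$planted_shares),
               tolerance = 1e-8)
  ## Eckart-Young: cumulative dPC variance never beats cumulative PCA
  expect_true(all(m$cumulative_ev <=
                    cumsum(m$pca_ev)[seq_along(m$cumulative_ev)] + 1e-10))
})

test_that("with data confined to one marginalization, dPCA matches PCA axes", {
  set.seed(53)
  N <- 25; Tn <- 60
  ## rank-3 force-confined data
  B <- matrix(rnorm(N * 3), N, 3)
  prof <- matrix(rnorm(3 * Tn), 3, Tn)
  x <- array(0, dim = c(N, 3, 2, Tn))
  cf <- c(-1, 0.2, 0.8); cf <- cf - mean(cf)
  for (f in 1:3) for (g in 1:2)
    x[, f, g, ] <- cf[f] * (B %*% prof)
  m <- dpca(x, lambda = 0)
  expect_true(all(m$marg == "force"))
  X <- graspdyn:::flatten4(x - graspdyn:::expand4(graspdyn:::mean_over(x, 1),
                                                  1, dim(x)))
  pc <- prcomp(t(X), center = FALSE)
  for (k in 1:2) {
    ang <- acos(min(1, abs(sum(m$encoder[, k] * pc$rotation[, k])) /
                      sqrt(sum(m$encoder[, k]^2) * sum(pc$rotation[, k]^2))))
    expect_lt(ang * 180 / pi, 1)
  }
})

test_that("degenerate marginalizations yield zero components", {
  set.seed(54)
  x <- array(rnorm(8 * 3 * 2 * 30), dim = c(8, 3, 2, 30))
  ## average out everything except pure time: keep only the t term
  mg <- marginalize(x)
  xt <- mg$terms$grand + mg$terms$t
  m <- dpca(xt)
  expect_true(all(m$marg == "condition_independent"))
  expect_setequal(m$dropped, c("force", "grip", "interaction"))
})

test_that("lambda selection is seeded and reproducible", {
  set.seed(55)
  ls <- latent_spec(n_units = 12, amplitude = 4)
  x5 <- simulate_rate_tensor(ls, n_trials = 6)
  m1 <- dpca(x5, lambda_repetitions = 3, seed = 9)
  m2 <- dpca(x5, lambda_repetitions = 3, seed = 9)
  expect_identical(m1$lambda, m2$lambda)
  expect_identical(m1$marg_shares, m2$marg_shares)
  expect_true(all(diff(m1$lambda_cv$grid) > 0) || 0 %in% m1$lambda_cv$grid)
})

test_that("decoding hits ceiling on separated classes and chance on shuffles", {
  set.seed(56)
  N <- 15; Tn <- 390; ntr <- 8
  x5 <- array(rnorm(N * 3 * 2 * Tn * ntr, 20, 2), c(N, 3, 2, Tn, ntr))
  sep <- matrix(rnorm(N), N)  # grip pattern, well above noise
  win <- 150:300
  x5[, , 2, win, ] <- x5[, , 2, win, ] + 10 * array(sep, c(N, 3, length(win), ntr))
  m_ax <- drop(sep / sqrt(sum(sep^2)))
  dec <- decode_over_time(m_ax, x5, "grip", cv_iterations = 30,
                          n_shuffles = 40, seed = 10)
  expect_gt(mean(dec$accuracy[win]), 0.95)
  expect_true(nrow(dec$intervals) >= 1)
  expect_true(any(dec$intervals$end - dec$intervals$start + 1 >= 10))
  ## shuffled labels: chance level for grip (1/2) and force (1/3)
  x0 <- array(rnorm(N * 3 * 2 * 60 * ntr, 20, 2), c(N, 3, 2, 60, ntr))
  dg <- decode_over_time(m_ax, x0, "grip", cv_iterations = 40,
                         n_shuffles = 0, seed = 11)
  df <- decode_over_time(m_ax, x0, "force", cv_iterations = 40,
                         n_shuffles = 0, seed = 12)
  se_g <- sd(dg$accuracy) / sqrt(length(dg$accuracy))
  se_f <- sd(df$accuracy) / sqrt(length(df$accuracy))
  expect_lt(abs(mean(dg$accuracy) - 1 / 2), 3 * se_g)
  expect_lt(abs(mean(df$accuracy) - 1 / 3), 3 * se_f)
})

test_that("significance intervals require at least ten consecutive bins", {
  sig <- rep(FALSE, 60)
  sig[11:19] <- TRUE          # 9 bins: not reported
  expect_equal(nrow(significant_intervals(sig, 10)), 0)
  sig[11:20] <- TRUE          # 10 bins: reported
  iv <- significant_intervals(sig, 10)
  expect_equal(iv$start, 11); expect_equal(iv$end, 20)
})

test_that("pseudo-trial assembly respects pools and simultaneity", {
  set.seed(57)
  pools <- list(1:6, 1:6, 1:6)
  pt <- make_pseudo_trials(pools, n_folds = 6)
  ## without replacement within a sweep: each trial used exactly once
  for (u in 1:3) expect_setequal(pt[u, ], 1:6)
  ## simultaneous recordings pass through as whole trials
  ps <- make_pseudo_trials(pools, n_folds = 4, simultaneous = TRUE)
  expect_true(all(apply(ps, 2, function(col) length(unique(col)) == 1)))
  ## disjoint per-unit pools stay valid per unit
  pools2 <- list(1:4, 11:14)
  p2 <- make_pseudo_trials(pools2, n_folds = 8)
  expect_true(all(p2[1, ] %in% 1:4) && all(p2[2, ] %in% 11:14))
})

test_that("dpca methods expose coefficients, predictions, and summaries", {
  set.seed(58)
  ls <- latent_spec(n_units = 10)
  x <- latent_rate_tensor(ls)
  m <- dpca(x)
  expect_equal(dim(coef(m)), c(length(m$ev), 10))
  expect_equal(dim(coef(m, "encoder")), c(10, length(m$ev)))
  pr <- predict(m, x)
  expect_equal(dim(pr), c(length(m$ev), 3 * 2 * dim(x)[4]))
  expect_equal(unname(pr[1, 1:5]),
               unname((m$decoder %*% graspdyn:::flatten4(
                 x - graspdyn:::expand4(m$center, 1, dim(x))))[1, 1:5]))
  s <- summary(m)
  expect_s3_class(s, "summary.dpca")
  expect_equal(nrow(s$components), length(m$ev))
  expect_output(print(m), "Demixed PCA")
})
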