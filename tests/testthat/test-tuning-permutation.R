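test_that("per-bin F statistics match the Type II ANOVA oracle", {
  set.seed(41)
  ## unbalanced cells after exclusions
  repeat {
    labels <- data.frame(
      grip = sample(rep(c("whole_hand", "precision"), c(20, 24))),
      force = sample(rep(c("low", "medium", "high"), c(16, 14, 14))))
    if (min(table(labels$grip, labels$force)) >= 2) break
  }
  rates <- matrix(rnorm(44 * 390, 20, 4), 44, 390)
  res <- test_unit(rates, labels, cluster_test_config(n_permutations = 20,
                                                      rng_seed = 1))
  for (b in c(1, 97, 390)) {
    d <- data.frame(y = rates[, b], grip = factor(labels$grip),
                    force = factor(labels$force))
    full <- lm(y ~ grip * force, d)
    gf <- lm(y ~ grip + force, d)
    ## Type II: each main effect adjusted for the other, interaction for both
    ss_g <- deviance(lm(y ~ force, d)) - deviance(gf)
    ss_f <- deviance(lm(y ~ grip, d)) - deviance(gf)
    ss_i <- deviance(gf) - deviance(full)
    mse <- deviance(full) / df.residual(full)
    expect_equal(res$effects$grip$F[b], ss_g / 1 / mse, tolerance = 1e-8)
    expect_equal(res$effects$force$F[b], ss_f / 2 / mse, tolerance = 1e-8)
    expect_equal(res$effects$interaction$F[b], ss_i / 2 / mse, tolerance = 1e-8)
  }
})

test_that("a planted force effect yields one force cluster in the hold epoch", {
  set.seed(42)
  hold_bins <- 281:370
  u <- simulate_unit_rates(n_trials = 20, baseline = 20,
                           force_levels = c(-15, 0, 15),
                           effect_bins = hold_bins)
  res <- test_unit(u$rates, u$labels, cluster_test_config(rng_seed = 7))
  sig_f <- significant_bins(res, "force")
  expect_true(any(sig_f[hold_bins]))
  expect_false(any(sig_f[1:170]))
  expect_false(any(significant_bins(res, "grip")))
  ## determinism under a fixed seed
  res2 <- test_unit(u$rates, u$labels, cluster_test_config(rng_seed = 7))
  expect_identical(res$effects$force$clusters, res2$effects$force$clusters)
  ## preferred force across the detected cluster
  expect_true(all(res$preferred_force[sig_f] == "high"))
})

test_that("clusters never span alignment-segment boundaries", {
  set.seed(43)
  u <- simulate_unit_rates(n_trials = 15, baseline = 20,
                           force_levels = c(-20, 0, 20),
                           effect_bins = 160:280)   # crosses both boundaries
  res <- test_unit(u$rates, u$labels, cluster_test_config(rng_seed = 3))
  cl <- res$effects$force$clusters
  for (i in seq_len(nrow(cl))) {
    expect_false(cl$start[i] <= 170 && cl$end[i] > 170)
    expect_false(cl$start[i] <= 270 && cl$end[i] > 270)
  }
})

test_that("population fractions count cluster coverage per bin", {
  mk <- function(sig_ranges) {
    eff <- list()
    for (e in c("grip", "force", "interaction")) {
      cl <- data.frame(start = integer(0), end = integer(0),
                       sum_F = numeric(0), significant = logical(0))
      if (!is.null(sig_ranges[[e]]))
        cl <- data.frame(start = sig_ranges[[e]][1], end = sig_ranges[[e]][2],
                         sum_F = 100, significant = TRUE)
      eff[[e]] <- list(clusters = cl, F = numeric(50))
    }
    structure(list(effects = eff), class = "cluster_test")
  }
  units <- list(mk(list(force = c(10, 19))), mk(list(force = c(15, 24))),
                mk(list(grip = c(1, 50))), mk(list()), mk(list()))
  fr <- population_fractions(units)
  ## manual enumeration over the 5 hand-built units
  expect_equal(unname(fr["force", 12]), 1 / 5)
  expect_equal(unname(fr["force", 17]), 2 / 5)
  expect_equal(unname(fr["force", 30]), 0)
  expect_equal(unname(fr["grip", 25]), 1 / 5)
  expect_equal(fr["interaction", ], rep(0, 50), ignore_attr = TRUE)
})

test_that("preferred force breaks exact ties toward lower force with a log", {
  fm <- rbind(low = c(5, 3, 7), medium = c(5, 9, 7), high = c(5, 1, 7))
  pf <- preferred_force(fm, sig_bins = c(TRUE, TRUE, TRUE))
  expect_equal(unclass(pf)[1:3], c("low", "medium", "low"), ignore_attr = TRUE)
  expect_equal(attr(pf, "ties"), c(1L, 3L))
})

test_that("doubling a planted effect never lowers detection", {
  set.seed(44)
  hit <- function(amp) {
    mean(replicate(8, {
      u <- simulate_unit_rates(n_trials = 12, baseline = 20,
                               force_levels = amp * c(-1, 0, 1),
                               effect_bins = 300:360)
      res <- test_unit(u$rates, u$labels,
                       cluster_test_config(n_permutations = 300))
      any(res$effects$force$clusters$significant)
    }))
  }
  expect_gte(hit(16), hit(8))
})
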