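test_that("response times are event differences with band-entry AT", {
  tt <- toy_trial_table(n = 6)
  i <- which(tt$force == "medium")[1]
  tt$t_go[i] <- 1000 + tt$t_start[i]
  tt$t_move[i] <- 1268 + tt$t_start[i]
  tt$t_touch[i] <- 1484 + tt$t_start[i]
  tt$t_acquired[i] <- tt$t_touch[i] + 450
  tt$t_reward[i] <- tt$t_acquired[i] + 1000
  tt$t_end[i] <- tt$t_reward[i] + 200
  bands <- task_config()$force_bands
  traces <- lapply(seq_len(nrow(tt)), function(j)
    toy_force_trace(tt[j, ], bands[[tt$force[j]]]))
  met <- compute_response_times(tt, traces, bands)
  expect_equal(met$RT[i], 268)
  expect_equal(met$MT[i], 216)
  expect_equal(met$AT[i], 450)
  ## force above the band minimum already at touch: AT clipped to 0
  i_low <- which(tt$force == "low")[1]
  expect_equal(met$AT[i_low], 0)
  ## force never reaching the band: AT undefined, trial flagged failed
  i_fail <- which(tt$force == "high")[1]
  traces[[i_fail]] <- toy_force_trace(tt[i_fail, ], c(9, 12), plateau = 4)
  met2 <- compute_response_times(tt, traces, bands)
  expect_true(is.na(met2$AT[i_fail]))
  expect_false(met2$success[i_fail])
})

test_that("exclusion thresholds are strict and counted per rule", {
  met <- data.frame(trial_id = 1:10, condition = "whole_hand.low",
                    RT = c(600, rep(250, 9)),
                    MT = c(200, 400, rep(200, 8)),
                    AT = c(100, 100, 1600, rep(100, 7)),
                    n_touches = c(1, 1, 1, 2, rep(1, 6)),
                    success = TRUE)
  ex <- exclude_trials(met)
  ## enumerated by hand: trials 1-4 each violate exactly one rule
  expect_equal(sum(ex$keep), 6)
  expect_equal(unname(ex$log[c("rt", "mt", "at", "multi_touch")]),
               c(1, 1, 1, 1))
  ## boundary values are retained (strict inequalities)
  met_edge <- data.frame(trial_id = 1, condition = "x", RT = 500, MT = 350,
                         AT = 1500, n_touches = 1, success = TRUE)
  expect_true(exclude_trials(met_edge)$keep)
  ## idempotent: re-applying to the retained set excludes nothing
  ex2 <- exclude_trials(met[ex$keep, ])
  expect_equal(sum(ex2$keep), 6)
})

test_that("force divergence reproduces the one-way ANOVA / t-test identity", {
  set.seed(11)
  tt <- toy_trial_table(n = 36)
  bands <- task_config()$force_bands
  ## identical per-condition trace sets: between-level variance is exactly 0
  traces_same <- lapply(seq_len(nrow(tt)), function(i)
    toy_force_trace(tt[i, ], c(0, 12), at_ms = 0,
                    plateau = 6 + 0.2 * (ceiling(i / 6) %% 3 - 1)))
  div <- compare_force_levels(traces_same, tt)
  expect_equal(unname(div$whole_hand$tukey[, "p adj"]), rep(1, 3))
  expect_equal(unname(div$precision$tukey[, "p adj"]), rep(1, 3))
  ## planted low << medium = high
  plat <- c(low = 1, medium = 6, high = 6)
  traces <- lapply(seq_len(nrow(tt)), function(i) {
    tr <- toy_force_trace(tt[i, ], c(0, 12), at_ms = 0,
                          plateau = plat[[tt$force[i]]])
    tr$samples <- tr$samples + rnorm(length(tr$samples), 0, 0.3)
    tr
  })
  div2 <- compare_force_levels(traces, tt)
  for (g in c("whole_hand", "precision")) {
    expect_lt(div2[[g]]$tukey["medium-low", "p adj"], 0.001)
    expect_gt(div2[[g]]$tukey["high-medium", "p adj"], 0.2)
  }
  ## two-group ANOVA p equals the equal-variance t-test p (F = t^2)
  y <- rnorm(20, 5, 1); grp <- rep(c("a", "b"), each = 10)
  y[grp == "b"] <- y[grp == "b"] + 0.8
  p_aov <- summary(aov(y ~ grp))[[1]][["Pr(>F)"]][1]
  p_t <- t.test(y ~ grp, var.equal = TRUE)$p.value
  expect_equal(p_aov, p_t, tolerance = 1e-12)
})

test_that("overshoot fractions count planted excursions exactly", {
  tt <- toy_trial_table(n = 10)
  tt$condition <- "whole_hand.medium"; tt$grip <- "whole_hand"
  tt$force <- "medium"
  bands <- task_config()$force_bands
  over <- c(rep(TRUE, 3), rep(FALSE, 7))
  traces <- lapply(seq_len(nrow(tt)), function(i)
    toy_force_trace(tt[i, ], bands$medium, at_ms = 100, plateau = 7,
                    overshoot = over[i]))
  os <- overshoot_fraction(traces, tt, bands)
  expect_equal(unname(os[["whole_hand.medium"]]), 0.3)
  ## none / all
  traces0 <- lapply(seq_len(nrow(tt)), function(i)
    toy_force_trace(tt[i, ], bands$medium, at_ms = 100, plateau = 7))
  expect_equal(unname(overshoot_fraction(traces0, tt, bands)[["whole_hand.medium"]]), 0)
  traces1 <- lapply(seq_len(nrow(tt)), function(i)
    toy_force_trace(tt[i, ], bands$medium, at_ms = 100, plateau = 7,
                    overshoot = TRUE))
  expect_equal(unname(overshoot_fraction(traces1, tt, bands)[["whole_hand.medium"]]), 1)
})

test_that("performance summary fractions are consistent per condition", {
  set.seed(12)
  cfg <- task_config(n_trials = 300, n_units = 2)
  s <- simulate_session(cfg, ls = latent_spec(n_units = 2), seed = 5)
  perf <- performance_summary(s$trial_table)
  expect_true(all(perf$success_after_cue >= 0 & perf$success_after_cue <= 1))
  expect_true(all(perf$success_after_go >= perf$success_after_cue - 1e-12))
  expect_true(all(perf$eye_fixation_error >= 0 & perf$eye_fixation_error <= 1))
})
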