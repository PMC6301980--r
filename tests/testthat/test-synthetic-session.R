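test_that("condition scheduler draws uniformly and keeps the pool bounded", {
  set.seed(1)
  cfg <- task_config(n_trials = 6000)
  sched <- schedule_conditions(cfg, outcomes = NULL)
  ## multinomial oracle: all-success draws are uniform over 6 conditions
  freq <- table(sched$condition) / nrow(sched)
  se3 <- 3 * sqrt((1 / 6) * (5 / 6) / 6000)
  expect_true(all(abs(freq - 1 / 6) < se3))
  expect_true(all(sched$pool_size >= cfg$pool_refill_threshold))
  expect_true(all(sched$pool_size <= cfg$pool_size))
})

test_that("a condition that always fails is drawn more often than 1/6", {
  set.seed(2)
  cfg <- task_config(n_trials = 3000)
  sched <- schedule_conditions(cfg, outcomes = function(cond)
    cond != "precision.high")
  expect_gt(mean(sched$condition == "precision.high"), 1 / 6)
})

test_that("simulated trials have causal events and exact acquisition times", {
  set.seed(3)
  cfg <- task_config(force_noise_sd = 0, overshoot_prob = 0)
  tr <- simulate_trial(cfg, "whole_hand.medium")
  ev <- tr$events
  expect_true(all(diff(ev[c("t_start", "cue_on", "cue_off", "go", "move",
                            "touch", "acquired", "reward")]) >= 0))
  ## degenerate AT distribution: band entry exactly at touch + 400 ms
  cfg400 <- task_config(at_mean = c(low = 0, medium = 400, high = 400),
                        at_sd = c(low = 0, medium = 0, high = 0),
                        force_noise_sd = 0, overshoot_prob = 0)
  tr <- simulate_trial(cfg400, "whole_hand.medium")
  ts <- tr$force$t0 + seq_along(tr$force$samples) - 1
  first_in <- ts[which(tr$force$samples >= 5 & ts >= tr$events[["touch"]])[1]]
  expect_equal(first_in - tr$events[["touch"]], 400)
  ## low-force trials are inside their band (minimum 0 N) at touch
  trl <- simulate_trial(cfg400, "precision.low")
  expect_equal(trl$events[["acquired"]], trl$events[["touch"]])
})

test_that("sampled acquisition times match the configured distribution", {
  set.seed(4)
  cfg <- task_config(force_noise_sd = 0, overshoot_prob = 0)
  at <- replicate(1000, {
    tr <- simulate_trial(cfg, "whole_hand.medium")
    tr$events[["acquired"]] - tr$events[["touch"]]
  })
  ## sampling oracle: mean of the truncated-at-0 normal the generator draws
  set.seed(41)
  ref <- rnorm(2e5, cfg$at_mean[["medium"]], cfg$at_sd[["medium"]])
  ref <- ref[ref >= 0]
  expect_lt(abs(mean(at) - mean(ref)), 3 * sd(at) / sqrt(length(at)))
})

test_that("latent coefficients are centered and planted variance is confined", {
  set.seed(5)
  ls <- latent_spec(n_units = 15)
  expect_lt(abs(mean(ls$latents$force$coef)), 1e-10)
  expect_lt(abs(mean(ls$latents$grip$coef)), 1e-10)
  expect_lt(max(abs(rowMeans(ls$latents$interaction$coef))), 1e-10)
  expect_lt(max(abs(colMeans(ls$latents$interaction$coef))), 1e-10)
  ## a spec with only a force latent puts zero variance elsewhere
  lf <- ls
  for (m in c("condition_independent", "grip", "interaction"))
    lf$weights[, m] <- 0
  x <- latent_rate_tensor(lf)
  mg <- marginalize(x)
  expect_equal(mg$shares[["force"]], 1, tolerance = 1e-10)
  expect_lt(mg$shares[["grip"]] + mg$shares[["interaction"]] +
              mg$shares[["condition_independent"]], 1e-10)
  ## planted shares agree with the marginalization algebra exactly
  mg_full <- marginalize(latent_rate_tensor(ls))
  expect_equal(unname(mg_full$shares), unname(ls$planted_shares),
               tolerance = 1e-10)
})

test_that("constant-rate population matches the Poisson oracle", {
  set.seed(6)
  ls <- latent_spec(n_units = 4, amplitude = 0,
                    baseline_range = c(20, 20))
  tt <- toy_trial_table(n = 30)
  spikes <- simulate_population(ls, tt)
  rt <- spikes_to_rates(spikes, tt)
  per_trial <- apply(rt$rates, c(1, 2), mean)
  se <- sd(per_trial) / sqrt(length(per_trial))
  expect_lt(abs(mean(per_trial) - 20), 3 * se)
})

test_that("EMG peaks around touch, is force-ordered, and silent before go", {
  set.seed(7)
  cfg <- task_config(n_trials = 120, n_units = 3, eye_error_prob = 0,
                     exec_failure_prob = 0)
  s <- simulate_session(cfg)
  tt <- s$trial_table
  fixwin <- cbind(tt$t_start, tt$t_cue_on)
  env <- preprocess_emg(s$emg$FDS, fixwin)
  x <- signal_to_tensor(env, tt)
  tl <- composite_timeline()
  peak_by_force <- apply(x[1, , , ], 1, max)
  expect_true(peak_by_force[["low"]] < peak_by_force[["medium"]])
  expect_true(peak_by_force[["medium"]] < peak_by_force[["high"]])
  ## peak location near touch
  prof <- apply(x[1, , , ], 3, mean)
  expect_equal(as.character(tl$segment[which.max(prof)]), "touch")
  ## normalized activity in the pre-go (cue-aligned) window stays at baseline
  pre_go <- tl$segment == "cue" & tl$center < 1200
  expect_lt(max(abs(prof[pre_go] - 1)), 0.15)
})

test_that("the same seed reproduces a session bit-identically", {
  cfg <- task_config(n_trials = 25, n_units = 5, rng_seed = 123)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$trial_table, s2$trial_table)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$emg$FDS$samples, s2$emg$FDS$samples)
})
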