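## Shared fixtures built in code.

## Balanced trial labels: n trials per condition, force fastest within grip.
balanced_labels <- function(n) {
  data.frame(grip = rep(rep(c("whole_hand", "precision"), each = 3), n),
             force = rep(c("low", "medium", "high"), 2 * n),
             stringsAsFactors = FALSE)
}

## A minimal successful trial table with integer events spaced like the task.
toy_trial_table <- function(n = 12, seed = 99) {
  set.seed(seed)
  conds <- task_conditions()
  idx <- rep(seq_len(6), length.out = n)
  t0 <- seq(0, by = 7000, length.out = n)
  cue <- t0 + 450
  go <- cue + 800 + 600
  move <- go + 260
  touch <- move + 210
  acq <- touch + c(low = 0, medium = 450, high = 550)[conds$force[idx]]
  data.frame(trial_id = seq_len(n), condition = conds$condition[idx],
             grip = as.character(conds$grip[idx]),
             force = as.character(conds$force[idx]),
             t_start = t0, t_cue_on = cue, t_cue_off = cue + 800,
             t_go = go, t_move = move, t_touch = touch, t_acquired = acq,
             t_reward = acq + 1000, t_end = acq + 1200,
             success = TRUE, failure_stage = NA_character_, n_touches = 1L,
             stringsAsFactors = FALSE)
}

## Synthetic force trace entering the band `at_ms` after touch, plateau
## inside the band, optional overshoot bump.
toy_force_trace <- function(row, band, at_ms = NULL, plateau = NULL,
                            overshoot = FALSE) {
  if (is.null(at_ms)) at_ms <- row$t_acquired - row$t_touch
  if (is.null(plateau)) plateau <- mean(band)
  n <- ceiling(row$t_end - row$t_start) + 1
  ts <- row$t_start + seq_len(n) - 1
  f <- numeric(n)
  rise <- ts >= row$t_move & ts < row$t_touch + at_ms
  f[rise] <- max(band[1], 0.4) * 0.9 *
    (ts[rise] - row$t_move) / (row$t_touch + at_ms - row$t_move)
  f[ts >= row$t_touch + at_ms] <- plateau
  if (overshoot) {
    ctr <- (row$t_touch + row$t_reward) / 2
    f <- f + (band[2] - plateau + 1) * exp(-0.5 * ((ts - ctr) / 60)^2)
  }
  continuous_signal(f, 1000, "N", t0 = row$t_start)
}
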