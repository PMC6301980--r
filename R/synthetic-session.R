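#' Task configuration for the delayed grasping session generator
#'
#' Encodes the structure of the delayed grasping task: epoch durations
#' (fixation 400-500 ms, cue 800 ms, memory 500-700 ms, hold 1 s), the three
#' force bands (low 0-5 N, medium 5-9 N, high 9-12 N) crossed with two grip
#' types, and the pseudo-random condition pool (30 trials, 5 copies of each
#' of the 6 conditions, refilled whenever fewer than 25 remain). Response
#' time distributions default to values typical of trained macaques
#' (RT ~ 268 +- 69 ms; MT ~ 216/220 ms for whole-hand/precision grips;
#' force acquisition slowest for high force).
#'
#' @param n_trials number of attempted trials in a session.
#' @param n_units number of simulated units.
#' @param fixation_range,memory_range ms intervals (uniform draws).
#' @param cue_duration,hold_duration ms.
#' @param force_bands named list low/medium/high of (min, max) in N;
#'   must be contiguous and ordered.
#' @param pool_size,pool_refill_threshold condition pool parameters;
#'   `pool_size` must be divisible by 6 and exceed the refill threshold.
#' @param rt_mean,rt_sd reaction time distribution (ms).
#' @param mt_mean,mt_sd movement time distribution per grip (ms).
#' @param at_mean,at_sd force acquisition time distribution per force level
#'   (ms); low-force acquisition is structurally near zero.
#' @param eye_error_prob per-condition probability of breaking eye fixation
#'   before the go signal.
#' @param exec_failure_prob per-condition probability of failing after go.
#' @param overshoot_prob per-condition probability that a successful trial
#'   transiently exceeds its band maximum before reward.
#' @param p_double_touch probability of registering two handle touches.
#' @param force_noise_sd measurement noise on the force trace (N).
#' @param force_rate,emg_rate sampling rates (Hz).
#' @param iti_range inter-trial interval range (ms).
#' @param rng_seed integer seed; a fixed seed makes the session bit-identical.
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_trials = 500, n_units = 100,
                        fixation_range = c(400, 500), cue_duration = 800,
                        memory_range = c(500, 700), hold_duration = 1000,
                        force_bands = list(low = c(0, 5), medium = c(5, 9),
                                           high = c(9, 12)),
                        pool_size = 30, pool_refill_threshold = 25,
                        rt_mean = 268, rt_sd = 69,
                        mt_mean = c(whole_hand = 216, precision = 220),
                        mt_sd = c(whole_hand = 32, precision = 42),
                        at_mean = c(low = 0, medium = 467, high = 555),
                        at_sd = c(low = 0, medium = 295, high = 381),
                        eye_error_prob = rep(0.08, 6),
                        exec_failure_prob = c(0.04, 0.04, 0.10, 0.11, 0.04, 0.10),
                        overshoot_prob = c(0.22, 0.68, 0.34, 0.14, 0.48, 0.34),
                        p_double_touch = 0.02, force_noise_sd = 0.02,
                        force_rate = 1000, emg_rate = 1000,
                        iti_range = c(1000, 2000), rng_seed = NULL) {
  stopifnot(pool_size %% 6 == 0, pool_refill_threshold < pool_size)
  b <- force_bands
  if (!identical(names(b), FORCES)) stop("force_bands must be named low/medium/high")
  if (!(b$low[2] == b$medium[1] && b$medium[2] == b$high[1]))
    stop("force bands must be contiguous and ordered low < medium < high")
  cfg <- as.list(environment())
  for (nm in c("eye_error_prob", "exec_failure_prob", "overshoot_prob")) {
    v <- cfg[[nm]]
    if (length(v) == 1) v <- rep(v, 6)
    names(v) <- task_conditions()$condition
    cfg[[nm]] <- v
  }
  structure(cfg, class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf("<task_config> %d trials, %d units, pool %d (refill < %d), seed %s\n",
              x$n_trials, x$n_units, x$pool_size, x$pool_refill_threshold,
              if (is.null(x$rng_seed)) "none" else x$rng_seed))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Latent specification: planted low-dimensional structure

## Default time profiles on the composite timeline. Profiles are designed to
## be flat across the touch-tail / reward-head span that duplicates real time
## when acquisition is fast, so alignment duplication does not distort the
## planted structure.
default_profiles <- function(timeline = composite_timeline()) {
  seg <- timeline$segment; ctr <- timeline$center
  p_ci <- numeric(nrow(timeline))
  p_ci[seg == "cue"] <- 0.45 * exp(-0.5 * ((ctr[seg == "cue"] - 150) / 100)^2)
  tt <- ctr[seg == "touch"]
  p_ci[seg == "touch"] <- 1.2 * exp(-0.5 * ((tt + 50) / 130)^2) * (tt < 150) +
    (tt >= 150) * 0.8
  rt <- ctr[seg == "reward"]
  p_ci[seg == "reward"] <- 0.8 * (rt < -300) +
    (rt >= -300) * (0.8 - 0.6 * (rt + 300) / 500)

  p_force <- numeric(nrow(timeline))
  cc <- ctr[seg == "cue"]
  p_force[seg == "cue"] <- 0.18 * exp(-0.5 * ((cc - 1200) / 180)^2)  # planning
  p_force[seg == "touch"] <- 1 / (1 + exp(-(tt - 80) / 60))
  p_force[seg == "reward"] <- 1 * (rt < -200) + (rt >= -200) * (1 - 0.5 * (rt + 200) / 400)

  p_grip <- numeric(nrow(timeline))
  p_grip[seg == "cue"] <- 0.3 * exp(-0.5 * ((cc - 400) / 200)^2)
  p_grip[seg == "touch"] <- pmax(0.35, exp(-0.5 * ((tt + 100) / 150)^2)) *
    (tt < 250) + (tt >= 250) * 0.35
  p_grip[seg == "reward"] <- 0.35 * (rt < -150) + (rt >= -150) * 0.35 * (1 - (rt + 150) / 350)

  p_int <- numeric(nrow(timeline))
  p_int[seg == "touch"] <- 1 / (1 + exp(-(tt - 150) / 70))
  p_int[seg == "reward"] <- 1 * (rt < -200) + (rt >= -200) * (1 - (rt + 200) / 400)

  list(condition_independent = p_ci, force = p_force,
       grip = p_grip, interaction = p_int)
}

## Per-condition coefficients: the force latent separates the low force
## condition early and strongly (low << medium < high, as observed in force,
## EMG and neural data); all coefficient sets average to zero over the
## factors they vary with, so each latent lands in a single marginalization.
default_coefs <- function() {
  f <- c(low = -1.1, medium = 0.3, high = 0.8)
  g <- c(whole_hand = -1, precision = 1)
  fg <- outer(g, c(1, -0.5, -0.5))        # doubly centered
  dimnames(fg) <- list(GRIPS, FORCES)
  list(condition_independent = 1,
       force = f / sqrt(mean(f^2)),
       grip = g / sqrt(mean(g^2)),
       interaction = fg / sqrt(mean(fg^2)))
}

#' Latent specification with planted marginalization structure
#'
#' Defines the ground-truth low-dimensional structure of a synthetic session:
#' one latent time course per marginalization (condition-independent, force,
#' grip, interaction), per-condition coefficients that average to zero across
#' the factors they vary over (so each latent contributes variance to exactly
#' one marginalization), random unit mixing weights, per-unit baseline rates,
#' and Poisson spiking. Latent amplitudes are scaled so the planted variance
#' shares approximate `target_shares`; the exact shares implied by the drawn
#' weights are recorded in `$planted_shares`.
#'
#' Mixing weights and baselines are drawn from the current RNG state; seed
#' before calling for reproducibility.
#'
#' @param n_units number of units.
#' @param target_shares named numeric, approximate variance shares of the
#'   four combined marginalizations (must sum to 1).
#' @param amplitude overall modulation scale in spikes/s (RMS across the
#'   planted tensor).
#' @param baseline_range per-unit baseline firing rate range (spikes/s).
#' @param profiles,coefs optional overrides of the default latent time
#'   profiles (length 390 each) and condition coefficients.
#' @param spec an [alignment_spec()].
#' @return An object of class `latent_spec` with elements `latents` (one per
#'   marginalization: profile, coefficients, amplitude), `weights`
#'   (unit x latent), `baseline`, `planted_shares`, `emg` (EMG mixing spec),
#'   and `timeline`.
#' @export
latent_spec <- function(n_units = 100,
                        target_shares = c(condition_independent = 0.70,
                                          force = 0.15, grip = 0.10,
                                          interaction = 0.05),
                        amplitude = 6, baseline_range = c(15, 25),
                        profiles = NULL, coefs = NULL,
                        spec = alignment_spec()) {
  stopifnot(abs(sum(target_shares) - 1) < 1e-8)
  timeline <- composite_timeline(spec)
  if (is.null(profiles)) profiles <- default_profiles(timeline)
  if (is.null(coefs)) coefs <- default_coefs()
  margs <- names(target_shares)
  check_centered_coefs(coefs)
  W <- matrix(0, n_units, length(margs), dimnames = list(NULL, margs))
  W[, "condition_independent"] <- runif(n_units, 0.2, 1)
  for (m in setdiff(margs, "condition_independent")) W[, m] <- runif(n_units, -1, 1)
  latents <- lapply(margs, function(m) {
    p <- profiles[[m]]
    pc <- if (m == "condition_independent") p - mean(p) else p
    cf <- coefs[[m]]
    ## scale so the expected tensor RMS of the latent matches its target share
    ew2 <- if (m == "condition_independent") (1 - 0.2^3) / (3 * 0.8) else 1 / 3
    amp <- amplitude * sqrt(target_shares[[m]] / (mean(pc^2) * mean(cf^2) * ew2))
    list(marg = m, profile = p, coef = cf, amplitude = amp)
  })
  names(latents) <- margs
  baseline <- runif(n_units, baseline_range[1], baseline_range[2])
  out <- structure(list(latents = latents, weights = W, baseline = baseline,
                        timeline = timeline, alignment = spec,
                        emg = default_emg_spec()),
                   class = "latent_spec")
  out$planted_shares <- planted_shares(out)
  out
}

check_centered_coefs <- function(coefs) {
  tol <- 1e-8
  if (abs(mean(coefs$force)) > tol) stop("force coefficients must average to zero")
  if (abs(mean(coefs$grip)) > tol) stop("grip coefficients must average to zero")
  fg <- coefs$interaction
  if (max(abs(rowMeans(fg))) > tol || max(abs(colMeans(fg))) > tol)
    stop("interaction coefficients must be doubly centered")
  invisible(TRUE)
}

#' @export
print.latent_spec <- function(x, ...) {
  cat(sprintf("<latent_spec> %d units, %d latents; planted shares:\n",
              length(x$baseline), length(x$latents)))
  print(round(x$planted_shares, 4))
  invisible(x)
}

## Expand a latent's coefficients to the 6-condition grid (grip x force).
coef_grid <- function(latent) {
  switch(latent$marg,
         condition_independent = matrix(1, 2, 3, dimnames = list(GRIPS, FORCES)),
         force = matrix(rep(latent$coef, each = 2), 2, 3,
                        dimnames = list(GRIPS, FORCES)),
         grip = matrix(rep(latent$coef, 3), 2, 3, dimnames = list(GRIPS, FORCES)),
         interaction = latent$coef)
}

## Exact variance shares of the planted structure, computed directly from the
## latent contributions (time-centered for the condition-independent latent);
## independent of the marginalization routines.
planted_shares <- function(ls) {
  ss <- vapply(names(ls$latents), function(m) {
    l <- ls$latents[[m]]
    p <- if (m == "condition_independent") l$profile - mean(l$profile) else l$profile
    cg <- coef_grid(l)
    sum(ls$weights[, m]^2) * l$amplitude^2 * sum(cg^2) * sum(p^2)
  }, 0)
  ss / sum(ss)
}

#' Noiseless planted rate tensor
#'
#' The trial-averaged firing-rate tensor (unit x force x grip x time) implied
#' by a latent specification, before Poisson noise. Rates are rectified at 0;
#' the fraction of tensor mass removed by rectification is attached as
#' attribute `clipped` (negligible at default amplitudes).
#'
#' @param ls a [latent_spec()].
#' @return 4-D array `[unit, force, grip, time]` in spikes/s.
#' @export
latent_rate_tensor <- function(ls) {
  nu <- length(ls$baseline); nt <- nrow(ls$timeline)
  x <- array(rep(ls$baseline, 3 * 2 * nt), dim = c(nu, 3, 2, nt),
             dimnames = list(NULL, FORCES, GRIPS, NULL))
  for (m in names(ls$latents)) {
    l <- ls$latents[[m]]
    cg <- coef_grid(l)                      # grip x force
    for (f in 1:3) for (g in 1:2)
      x[, f, g, ] <- x[, f, g, ] +
        (ls$weights[, m] * l$amplitude * cg[g, f]) %o% l$profile
  }
  neg <- sum(pmin(x, 0)^2)
  x <- pmax(x, 0)
  attr(x, "clipped") <- neg / sum(x^2)
  x
}

## ---------------------------------------------------------------------------
## Condition scheduler

#' Pseudo-random condition scheduling from a replenished pool
#'
#' Draws conditions uniformly from a pool that starts with
#' `pool_size / 6` copies of each of the six conditions. A successful trial
#' removes the drawn copy; a failed trial leaves it in the pool (so failed
#' conditions recur more often and cannot be skipped); whenever the pool
#' holds fewer than `pool_refill_threshold` trials, one copy of every
#' condition is added, keeping the pool size between the threshold and
#' `pool_size`.
#'
#' @param config a [task_config()].
#' @param outcomes success flags: a logical vector of length `n_trials`, a
#'   function `condition -> logical`, or NULL (all successful).
#' @return Data frame with columns `condition`, `success`, `pool_size`
#'   (pool size after the draw, removal and any refill).
#' @export
schedule_conditions <- function(config, outcomes = NULL) {
  conds <- task_conditions()$condition
  counts <- setNames(rep(config$pool_size / 6, 6), conds)
  n <- config$n_trials
  cond <- character(n); succ <- logical(n); psize <- integer(n)
  for (i in seq_len(n)) {
    ci <- sample(conds, 1, prob = counts)
    ok <- if (is.null(outcomes)) TRUE
          else if (is.function(outcomes)) outcomes(ci)
          else outcomes[i]
    if (ok) counts[ci] <- counts[ci] - 1
    if (sum(counts) < config$pool_refill_threshold) counts <- counts + 1
    cond[i] <- ci; succ[i] <- ok; psize[i] <- sum(counts)
  }
  data.frame(condition = cond, success = succ, pool_size = psize,
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Single-trial simulation

rtrunc_norm <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(x < lower)) x[x < lower] <- rnorm(sum(x < lower), mean, sd)
  x
}

#' Simulate one trial: event times and force trace
#'
#' Draws epoch durations and response times from the configured
#' distributions, then builds a grasp-force trace: zero until movement
#' onset, a logistic rise that first reaches the condition's band minimum
#' exactly at `touch + AT`, a plateau inside the band held through the hold
#' epoch, and (with configured probability) a transient overshoot above the
#' band maximum before reward. Low-force trials enter their band (minimum
#' 0 N) at touch, so their acquisition time is structurally ~0. Event times
#' are rounded to 1 ms.
#'
#' @param config a [task_config()].
#' @param condition one of the six condition labels.
#' @param t_start absolute trial start time (ms).
#' @param success logical; failed trials are truncated at `failure_stage`.
#' @param failure_stage one of "fixation", "cue", "memory", "hold" for
#'   failed trials.
#' @return List with `events` (named vector: t_start, cue_on, cue_off, go,
#'   move, touch, acquired, reward, end; NA beyond a failure), `force`
#'   (a [continuous_signal()] or NULL before touch), `overshoot`,
#'   `n_touches`.
#' @export
simulate_trial <- function(config, condition, t_start = 0, success = TRUE,
                           failure_stage = NA_character_) {
  tc <- task_conditions()
  row <- match(condition, tc$condition)
  if (is.na(row)) stop("invalid condition label: ", condition)
  grip <- as.character(tc$grip[row]); force <- as.character(tc$force[row])
  band <- config$force_bands[[force]]

  ev <- c(t_start = t_start,
          cue_on = NA, cue_off = NA, go = NA, move = NA, touch = NA,
          acquired = NA, reward = NA, end = NA)
  stage_reached <- function(s) is.na(failure_stage) ||
    match(failure_stage, c("fixation", "cue", "memory", "hold")) >
    match(s, c("fixation", "cue", "memory", "hold"))

  if (!success && failure_stage == "fixation") {
    ev["end"] <- round(t_start + runif(1, 100, 400))
    return(list(events = ev, force = NULL, overshoot = FALSE, n_touches = 0L))
  }
  ev["cue_on"] <- round(t_start + runif(1, config$fixation_range[1],
                                        config$fixation_range[2]))
  if (!success && failure_stage == "cue") {
    ev["end"] <- round(ev[["cue_on"]] + runif(1, 50, config$cue_duration))
    return(list(events = ev, force = NULL, overshoot = FALSE, n_touches = 0L))
  }
  ev["cue_off"] <- ev[["cue_on"]] + config$cue_duration
  if (!success && failure_stage == "memory") {
    ev["end"] <- round(ev[["cue_off"]] + runif(1, 50, config$memory_range[1]))
    return(list(events = ev, force = NULL, overshoot = FALSE, n_touches = 0L))
  }
  ev["go"] <- round(ev[["cue_off"]] + runif(1, config$memory_range[1],
                                            config$memory_range[2]))
  ev["move"] <- round(ev[["go"]] + rtrunc_norm(1, config$rt_mean, config$rt_sd, 120))
  ev["touch"] <- round(ev[["move"]] +
                         rtrunc_norm(1, config$mt_mean[[grip]], config$mt_sd[[grip]], 60))

  hold_fail <- !success && failure_stage == "hold"
  at <- if (force == "low") 0
        else round(rtrunc_norm(1, config$at_mean[[force]], config$at_sd[[force]], 0))
  if (!hold_fail) {
    ev["acquired"] <- ev[["touch"]] + at
    ev["reward"] <- ev[["acquired"]] + config$hold_duration
    ev["end"] <- ev[["reward"]] + 200
  } else {
    ev["end"] <- ev[["touch"]] + 1500
  }

  ## force trace at config$force_rate (1 kHz): logistic rise crossing the
  ## band minimum exactly at touch + AT, plateau inside the band
  dur <- ceiling(ev[["end"]] - t_start) + 1L
  ts <- t_start + seq_len(dur) - 1
  plateau <- if (hold_fail) max(0.5, band[1] * 0.7)
             else band[1] + (0.35 + 0.3 * runif(1)) * (band[2] - band[1])
  bmin_eff <- max(band[1], 0.5)
  s <- 60
  m <- ev[["touch"]] + at + s * log(plateau / min(bmin_eff, plateau * 0.95) - 1)
  f <- plateau / (1 + exp(-(ts - m) / s))
  f[ts < ev[["move"]]] <- 0
  if (!hold_fail && !is.na(ev[["reward"]]))            # release after reward
    f[ts > ev[["reward"]]] <- f[ts > ev[["reward"]]] *
      exp(-(ts[ts > ev[["reward"]]] - ev[["reward"]]) / 150)
  overshoot <- FALSE
  if (!hold_fail && runif(1) < config$overshoot_prob[[condition]]) {
    overshoot <- TRUE
    ctr <- runif(1, ev[["acquired"]] + 150, ev[["reward"]] - 150)
    amp <- (band[2] - plateau) + runif(1, 0.3, 1.2)
    f <- f + amp * exp(-0.5 * ((ts - ctr) / 70)^2)
  }
  if (config$force_noise_sd > 0) f <- f + rnorm(dur, 0, config$force_noise_sd)
  n_touches <- 1L + (success && runif(1) < config$p_double_touch)
  list(events = ev,
       force = continuous_signal(f, config$force_rate, "N", t0 = t_start),
       overshoot = overshoot, n_touches = as.integer(n_touches))
}

## ---------------------------------------------------------------------------
## Mapping composite-timeline profiles into trial real time

## Upsample per-condition composite-bin rates to 1 ms. Returns [unit, ms, cond]
## with ms positions 1..3900 (cue 1..1700, touch 1701..2700, reward 2701..3900).
upsample_cond_rates <- function(ls) {
  x <- latent_rate_tensor(ls)                   # unit x force x grip x bin
  tl <- ls$timeline
  nu <- dim(x)[1]
  ends <- attr(tl, "segment_ends")
  starts <- c(1L, head(ends, -1) + 1L)
  n_ms <- sum(vapply(ls$alignment$windows, diff, 0))
  out <- array(0, dim = c(nu, n_ms, 6))
  ms_off <- 0L
  for (si in seq_along(ends)) {
    bins <- starts[si]:ends[si]
    w <- ls$alignment$windows[[si]]
    tq <- seq(w[1] + 0.5, w[2] - 0.5)           # 1-ms sample offsets
    ci <- 0L
    for (g in 1:2) for (f in 1:3) {
      ci <- ci + 1L
      vals <- t(apply(x[, f, g, bins, drop = FALSE], 1, function(v)
        approx(tl$center[bins], v, tq, rule = 2)$y))
      out[, ms_off + seq_along(tq), ci] <- vals
    }
    ms_off <- ms_off + length(tq)
  }
  dimnames(out) <- list(NULL, NULL, condition_of(rep(GRIPS, each = 3), rep(FORCES, 2)))
  out
}

## For one trial, map each 1-ms sample of [t_start, end) to composite 1-ms
## positions. Earlier alignment windows take precedence in overlaps; gaps are
## bridged by linear interpolation between the flanking assigned positions.
## Returns list(ts, idx1, idx2, w); samples with idx1 == 0 have no anchor.
trial_time_map <- function(events, spec = alignment_spec()) {
  t0 <- events[["t_start"]]
  n <- ceiling(events[["end"]] - t0)
  ts <- t0 + seq_len(n) - 0.5
  pos <- rep(NA_integer_, n)
  offs <- c(0L, cumsum(vapply(spec$windows, diff, 0)))
  anchors <- c(cue = "cue_on", touch = "touch", reward = "reward")
  for (si in seq_along(spec$windows)) {
    evt <- events[[anchors[[names(spec$windows)[si]]]]]
    if (is.na(evt)) next
    w <- spec$windows[[si]]
    sel <- which(is.na(pos) & ts >= evt + w[1] & ts < evt + w[2])
    pos[sel] <- offs[si] + floor(ts[sel] - (evt + w[1])) + 1L
  }
  idx1 <- pos; idx2 <- pos; wgt <- numeric(n)
  has <- which(!is.na(pos))
  if (length(has)) {
    if (has[1] > 1) { idx1[1:(has[1] - 1)] <- idx2[1:(has[1] - 1)] <- pos[has[1]] }
    last <- has[length(has)]
    if (last < n) { idx1[(last + 1):n] <- idx2[(last + 1):n] <- pos[last] }
    gaps <- which(diff(has) > 1)
    for (gi in gaps) {
      a <- has[gi]; b <- has[gi + 1]
      k <- (a + 1):(b - 1)
      idx1[k] <- pos[a]; idx2[k] <- pos[b]
      wgt[k] <- (k - a) / (b - a)
    }
  } else idx1[] <- idx2[] <- 0L
  list(ts = ts, idx1 = idx1, idx2 = idx2, w = wgt)
}

## ---------------------------------------------------------------------------
## Population spiking and EMG

#' Simulate population spike trains for a trial table
#'
#' Builds each trial's firing-rate profile in real time by anchoring the
#' planted latent time courses to the trial's actual events (cue onset,
#' touch, reward; earlier alignment windows take precedence where windows
#' overlap, and gaps between windows are bridged linearly), rectifies at 0,
#' and draws inhomogeneous Poisson spikes at 1 ms resolution. Trials that
#' failed before the cue run at baseline.
#'
#' @param ls a [latent_spec()]; baselines must be non-negative.
#' @param trial_table trial table as produced by [simulate_session()].
#' @return List of numeric vectors, one per unit, of absolute spike times
#'   (ms).
#' @export
simulate_population <- function(ls, trial_table) {
  if (any(ls$baseline < 0)) stop("negative baseline rate")
  C <- upsample_cond_rates(ls)                    # unit x ms x cond
  nu <- dim(C)[1]
  spikes <- vector("list", nu)
  for (u in seq_len(nu)) spikes[[u]] <- vector("list", nrow(trial_table))
  for (i in seq_len(nrow(trial_table))) {
    ev <- trial_events(trial_table[i, ])
    map <- trial_time_map(ev, ls$alignment)
    n <- length(map$ts)
    if (map$idx1[1] == 0L || is.na(ev[["cue_on"]])) {
      R <- matrix(ls$baseline, nu, n)
    } else {
      Cc <- C[, , trial_table$condition[i], drop = FALSE]
      dim(Cc) <- dim(C)[1:2]
      R <- Cc[, map$idx1, drop = FALSE] * rep(1 - map$w, each = nu) +
        Cc[, map$idx2, drop = FALSE] * rep(map$w, each = nu)
    }
    P <- pmin(pmax(R, 0), 1000) / 1000
    hits <- which(matrix(runif(nu * n), nu, n) < P, arr.ind = TRUE)
    if (nrow(hits)) {
      tms <- map$ts[hits[, 2]]
      sp <- split(tms, hits[, 1])
      for (nm in names(sp)) spikes[[as.integer(nm)]][[i]] <- sort(sp[[nm]])
    }
  }
  lapply(spikes, function(l) as.numeric(unlist(l)))
}

default_emg_spec <- function() {
  ## muscle activity is dominated by the common reach-and-grasp envelope;
  ## force modulates the envelope modestly and grip type barely
  list(muscles = c("FDS", "EDC"),
       weights = rbind(FDS = c(condition_independent = 1.0, force = 0.20,
                               grip = 0.15),
                       EDC = c(condition_independent = 0.85, force = 0.16,
                               grip = -0.12)),
       tone = 1, carrier_band = c(25, 250), sensor_noise_sd = 0.02)
}

## Per-condition EMG envelope on the 1-ms composite grid [ms, cond, muscle].
## Latent contributions are gated off before the go signal: the cue-aligned
## window always ends at or before go, so the gate simply zeroes the
## cue-window part of the movement-related profiles.
emg_envelopes <- function(ls) {
  tl <- ls$timeline
  prof <- list(condition_independent = ls$latents$condition_independent$profile,
               force = ls$latents$force$profile,
               grip = ls$latents$grip$profile)
  ## movement gating: no modulation in the cue-aligned window
  gate <- as.numeric(tl$segment != "cue")
  es <- ls$emg
  n_ms <- sum(vapply(ls$alignment$windows, diff, 0))
  env <- array(es$tone, dim = c(n_ms, 6, nrow(es$weights)),
               dimnames = list(NULL, condition_of(rep(GRIPS, each = 3),
                                                  rep(FORCES, 2)), es$muscles))
  coefs <- list(condition_independent = matrix(1, 2, 3),
                force = coef_grid(ls$latents$force),
                grip = coef_grid(ls$latents$grip))
  ends <- attr(tl, "segment_ends"); starts <- c(1L, head(ends, -1) + 1L)
  for (mu in seq_len(nrow(es$weights))) {
    ci <- 0L
    for (g in 1:2) for (f in 1:3) {
      ci <- ci + 1L
      v <- numeric(nrow(tl))
      for (m in names(prof))
        v <- v + es$weights[mu, m] * coefs[[m]][g, f] * prof[[m]] * gate
      ms_off <- 0L
      for (si in seq_along(ends)) {
        bins <- starts[si]:ends[si]
        w <- ls$alignment$windows[[si]]
        tq <- seq(w[1] + 0.5, w[2] - 0.5)
        env[ms_off + seq_along(tq), ci, mu] <- es$tone +
          approx(tl$center[bins], v[bins], tq, rule = 2)$y
        ms_off <- ms_off + length(tq)
      }
    }
  }
  pmax(env, 0)
}

#' Simulate raw surface EMG for a session
#'
#' EMG is modeled as a band-limited noise carrier (25-250 Hz) amplitude-
#' modulated by a rectified envelope mixing the condition-independent and
#' force latents (plus a small grip contribution), anchored to each trial's
#' events and gated off before the go signal. Peak activity occurs around
#' touch, ordered low < medium < high in force. Between trials and during
#' fixation the envelope sits at baseline muscle tone.
#'
#' @param ls a [latent_spec()].
#' @param trial_table trial table as produced by [simulate_session()].
#' @param rate sampling rate in Hz (1 kHz default).
#' @return Named list of [continuous_signal()] objects, one per muscle, plus
#'   attribute `envelope` holding the noiseless per-muscle envelopes.
#' @export
simulate_emg <- function(ls, trial_table, rate = 1000) {
  env_cond <- emg_envelopes(ls)                 # ms x cond x muscle
  t_end <- max(trial_table$t_end, na.rm = TRUE) + 500
  n <- ceiling(t_end * rate / 1000)
  es <- ls$emg
  out <- list()
  envs <- matrix(es$tone, n, length(es$muscles),
                 dimnames = list(NULL, es$muscles))
  for (i in seq_len(nrow(trial_table))) {
    ev <- trial_events(trial_table[i, ])
    if (is.na(ev[["cue_on"]])) next
    map <- trial_time_map(ev, ls$alignment)
    if (map$idx1[1] == 0L) next
    smp <- floor(map$ts * rate / 1000) + 1L
    keep <- smp >= 1 & smp <= n
    for (mu in seq_along(es$muscles)) {
      e <- env_cond[, trial_table$condition[i], mu]
      envs[smp[keep], mu] <- e[map$idx1[keep]] * (1 - map$w[keep]) +
        e[map$idx2[keep]] * map$w[keep]
    }
  }
  for (mu in seq_along(es$muscles)) {
    carrier <- butter_zerophase(rnorm(n), n = 3, cutoff_hz = es$carrier_band,
                                rate = rate, type = "pass")
    raw <- envs[, mu] * carrier + rnorm(n, 0, es$sensor_noise_sd)
    out[[es$muscles[mu]]] <- continuous_signal(raw, rate, "uV", t0 = 0)
  }
  attr(out, "envelope") <- envs
  out
}

## ---------------------------------------------------------------------------
## Whole-session assembly

trial_events <- function(row) {
  c(t_start = row$t_start, cue_on = row$t_cue_on, cue_off = row$t_cue_off,
    go = row$t_go, move = row$t_move, touch = row$t_touch,
    acquired = row$t_acquired, reward = row$t_reward, end = row$t_end)
}

#' Generate a complete synthetic delayed-grasping session
#'
#' Runs the condition scheduler with per-condition eye-fixation-error and
#' execution-failure probabilities, simulates every trial's events and force
#' trace, then generates population spike trains and surface EMG from the
#' planted latent structure. The same seed yields a bit-identical session.
#'
#' @param config a [task_config()].
#' @param ls a [latent_spec()], or NULL to draw one with `config$n_units`
#'   units (from the session seed).
#' @param seed integer seed; defaults to `config$rng_seed`.
#' @return Object of class `grasp_session`: list with `trial_table`,
#'   `spikes` (per unit), `emg` (per muscle), `force` (per trial),
#'   `ground_truth` (latent spec, planted shares, overshoot flags),
#'   `config`.
#' @export
simulate_session <- function(config = task_config(), ls = NULL,
                             seed = config$rng_seed) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ls)) ls <- latent_spec(n_units = config$n_units)
  conds <- task_conditions()$condition
  stage <- character(0)
  outcome_fn <- function(cond) {
    if (runif(1) < config$eye_error_prob[[cond]]) {
      stage <<- c(stage, sample(c("fixation", "cue", "memory"), 1)); FALSE
    } else if (runif(1) < config$exec_failure_prob[[cond]]) {
      stage <<- c(stage, "hold"); FALSE
    } else { stage <<- c(stage, NA_character_); TRUE }
  }
  sched <- schedule_conditions(config, outcome_fn)

  n <- nrow(sched)
  tc <- task_conditions()
  rows <- vector("list", n); forces <- vector("list", n)
  overshoot <- logical(n)
  t0 <- 0
  for (i in seq_len(n)) {
    tr <- simulate_trial(config, sched$condition[i], t_start = t0,
                         success = sched$success[i], failure_stage = stage[i])
    ev <- tr$events
    ri <- match(sched$condition[i], tc$condition)
    rows[[i]] <- data.frame(
      trial_id = i, condition = sched$condition[i],
      grip = as.character(tc$grip[ri]), force = as.character(tc$force[ri]),
      t_start = ev[["t_start"]], t_cue_on = ev[["cue_on"]],
      t_cue_off = ev[["cue_off"]], t_go = ev[["go"]], t_move = ev[["move"]],
      t_touch = ev[["touch"]], t_acquired = ev[["acquired"]],
      t_reward = ev[["reward"]], t_end = ev[["end"]],
      success = sched$success[i], failure_stage = stage[i],
      n_touches = tr$n_touches, stringsAsFactors = FALSE)
    forces[[i]] <- tr$force
    overshoot[i] <- tr$overshoot
    t0 <- ev[["end"]] + round(runif(1, config$iti_range[1], config$iti_range[2]))
  }
  trial_table <- do.call(rbind, rows)
  spikes <- simulate_population(ls, trial_table)
  emg <- simulate_emg(ls, trial_table, rate = config$emg_rate)
  structure(list(trial_table = trial_table, spikes = spikes, emg = emg,
                 force = forces,
                 ground_truth = list(latents = ls,
                                     planted_shares = ls$planted_shares,
                                     overshoot = overshoot,
                                     pool_sizes = sched$pool_size),
                 config = config),
            class = "grasp_session")
}

#' @export
print.grasp_session <- function(x, ...) {
  tt <- x$trial_table
  cat(sprintf("<grasp_session> %d trials (%d successful), %d units, %d muscles\n",
              nrow(tt), sum(tt$success), length(x$spikes), length(x$emg)))
  cat("planted variance shares:\n")
  print(round(x$ground_truth$planted_shares, 4))
  invisible(x)
}

#' Simulate one unit's trial-resolved rates on the composite timeline
#'
#' Calibration-study generator: Poisson spike trains at 1 ms resolution with
#' a constant baseline rate, optionally offset by additive force and grip
#' effects confined to a set of analysis bins, passed through the standard
#' smoothing/binning pipeline. With all effects zero the six conditions have
#' identical rate statistics (a null unit).
#'
#' @param n_trials trials per condition.
#' @param baseline baseline rate in spikes/s.
#' @param force_levels additive offsets (spikes/s) per force level within
#'   `effect_bins`.
#' @param grip_levels additive offsets per grip type within `effect_bins`.
#' @param effect_bins indices of 10 ms analysis bins carrying the effects.
#' @param spec an [alignment_spec()].
#' @return List with `rates` (trial x bin matrix, spikes/s) and `labels`
#'   (data frame with `grip`, `force`).
#' @export
simulate_unit_rates <- function(n_trials = 20, baseline = 20,
                                force_levels = c(0, 0, 0),
                                grip_levels = c(0, 0),
                                effect_bins = integer(0),
                                spec = alignment_spec()) {
  K <- composite_smoother(spec)
  n_ms <- sum(vapply(spec$windows, diff, 0))
  nb <- n_bins(spec)
  ms_of_bins <- unlist(lapply(effect_bins, function(b) ((b - 1) * 10 + 1):(b * 10)))
  rates <- matrix(0, 6 * n_trials, nb)
  labels <- data.frame(grip = rep(rep(GRIPS, each = 3), n_trials),
                       force = rep(FORCES, 2 * n_trials),
                       stringsAsFactors = FALSE)
  for (g in 1:2) for (f in 1:3) {
    r_ms <- rep(baseline, n_ms)
    r_ms[ms_of_bins] <- r_ms[ms_of_bins] + force_levels[f] + grip_levels[g]
    p <- pmin(pmax(r_ms, 0), 1000) / 1000
    rows <- which(labels$grip == GRIPS[g] & labels$force == FORCES[f])
    sp <- (matrix(runif(n_ms * n_trials), n_ms, n_trials) < p) * 1000
    rates[rows, ] <- t(as.matrix(K %*% sp))
  }
  list(rates = rates, labels = labels)
}

#' Simulate a trial-resolved rate tensor on the composite timeline
#'
#' Shortcut generator for calibration and recovery studies: produces the
#' 5-D tensor (unit x force x grip x time x trial) directly on the canonical
#' composite timeline, bypassing event jitter. With `noise = "poisson"`,
#' 1 ms Bernoulli spike trains are drawn at the planted rates and passed
#' through the standard smoothing/binning pipeline (Gaussian sigma 50 ms,
#' 10 ms bins); with `noise = "none"` the planted rates are replicated.
#'
#' @param ls a [latent_spec()].
#' @param n_trials trials per condition.
#' @param noise "poisson" or "none".
#' @return 5-D array `[unit, force, grip, time, trial]` (spikes/s).
#' @export
simulate_rate_tensor <- function(ls, n_trials = 20, noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  x <- latent_rate_tensor(ls)
  nu <- dim(x)[1]; nb <- dim(x)[4]
  out <- array(0, dim = c(nu, 3, 2, nb, n_trials),
               dimnames = c(dimnames(x), list(NULL)))
  if (noise == "none") {
    for (tr in seq_len(n_trials)) out[, , , , tr] <- x
    return(out)
  }
  C <- upsample_cond_rates(ls)                  # unit x ms x cond
  spec <- ls$alignment
  n_ms <- dim(C)[2]
  K <- composite_smoother(spec)                 # bins x ms sparse operator
  ci <- 0L
  for (g in 1:2) for (f in 1:3) {
    ci <- ci + 1L
    P <- t(pmin(pmax(C[, , ci], 0), 1000) / 1000)      # ms x unit
    for (tr in seq_len(n_trials)) {
      spikes01 <- (matrix(runif(n_ms * nu), n_ms, nu) < P) * 1000
      out[, f, g, , tr] <- t(as.matrix(K %*% spikes01))
    }
  }
  out
}
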