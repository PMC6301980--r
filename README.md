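# graspdyn

Tools for quantifying how neural populations encode **grip type** and
**grasp force** in a delayed grasping task, in which a primate grasps an
instrumented handle with a whole-hand or precision grip at a low (0–5 N),
medium (5–9 N), or high (9–12 N) force level after a variable memory
delay.

The package implements the complete analysis chain for such recordings:

* **Behavior** — reaction / movement / force-acquisition times, strict
  exclusion rules (RT > 0.5 s, MT > 0.35 s, AT > 1.5 s, multiple touches),
  per-condition performance, early force divergence (ANOVA +
  Tukey–Kramer on the first 100 ms after touch), and overshoot fractions.
* **Signal conditioning** — unit-sum Gaussian smoothing, EMG band-pass
  (25–250 Hz) / rectify / fixation-normalize, running-median high-pass
  (3.33 ms), zero-phase Butterworth low-pass, and PCA common-artifact
  cancellation with the 0.36 loading-retention rule.
* **Rate estimation** — firing rates on a three-alignment composite
  timeline (cue −400..+1300 ms, touch −500..+500 ms, reward −1000..+200 ms;
  σ = 50 ms smoothing; 390 analysis bins of 10 ms), with masking and
  linear interpolation of the touch/reward alignment overlap.
* **Tuning** — a cluster-based permutation test per unit: two-way ANOVA
  in 10 ms steps, clusters of adjacent bins with p < 0.01, summed F
  against a 1000-permutation max-cluster null at the 99th percentile,
  separately for the grip, force, and interaction effects; population
  tuning fractions and preferred-force labels.
* **Demixed PCA** — the marginalization algebra
  (x̄, x̄_t, x̄_f, x̄_g, x̄_tf, x̄_tg, x̄_fg, x̄_tfg; condition-independent =
  x̄_t, force = x̄_f + x̄_tf, grip = x̄_g + x̄_tg, interaction =
  x̄_fg + x̄_tfg), a reduced-rank ridge dPCA fit
  (min ‖X_φ − D_φF_φX‖² + λ‖D_φF_φ‖², λ cross-validated on held-out
  trials), explained-variance accounting, and time-resolved decoding with
  a shuffle-based significance rule (accuracy above **all** 100 shuffles
  in ≥ 10 consecutive bins).
* **EMG correlation** — per-muscle EMG marginalizations correlated with
  the two largest demixed components per factor under a −500..+500 ms
  time-shift search anchored on the condition-independent component.
* **Synthetic sessions** — a generator that reproduces the task structure
  (epoch durations, force bands, the 30-trial condition pool with refill
  below 25) and plants known latent structure, so every stage above is
  testable without any recorded data.

## Worked example

```r
library(graspdyn)

cfg <- task_config(n_trials = 200, n_units = 40, rng_seed = 1)
session <- simulate_session(cfg)
session
#> <grasp_session> 200 trials (175 successful), 40 units, 2 muscles
#> planted variance shares:
#> condition_independent                 force                  grip
#>                0.7408                0.1263                0.0929
#>           interaction
#>                0.0400

## behavioral filtering
metrics <- compute_response_times(session$trial_table, session$force,
                                  cfg$force_bands)
excl <- exclude_trials(metrics)
excl$log
#>          rt           mt           at  multi_touch unsuccessful
#>           0            0            0            4           25

tt <- session$trial_table
tt$success <- tt$success & excl$keep

## rates on the composite timeline, with the alignment overlap interpolated
rates <- spikes_to_rates(session$spikes, tt)
rates <- mask_and_interpolate(rates, median_at_per_condition(tt))

## cluster-based permutation test for one unit
test_unit(rates$rates[1, , ], rates$trials,
          cluster_test_config(rng_seed = 11), rates$timeline)
#> <cluster_test> 171 trials, 1000 permutations, alpha = 0.01
#>   grip       : 1 cluster(s), 0 significant (null thr 168.7)
#>   force      : 3 cluster(s), 3 significant (null thr 102.3)
#>   interaction: 3 cluster(s), 3 significant (null thr 104.1)

## demixed PCA on the trial-resolved tensor
model <- dpca(as_tensor5d(rates), seed = 2)
model
#> Demixed PCA: 30 components over 40 units, lambda = 0.00316228
#> marginalization variance shares:
#> condition_independent                 force                  grip
#>                0.7461                0.1225                0.0920
#>           interaction
#>                0.0394
#> top component: condition_independent (64.5% of variance); first 30 components: 93.4%

## EMG marginalizations vs. demixed components
fixwin <- cbind(tt$t_start, tt$t_cue_on)
margs <- lapply(session$emg, function(m)
  marginalize(signal_to_tensor(preprocess_emg(m, fixwin), tt)))
correlate_components(margs, model)
#> EMG-neural correlation: chosen shift +20 ms (positive = neural leads)
#>                        dPC1  dPC2
#> condition_independent 0.925 0.063
#> force                 0.891 0.001
#> grip                  0.088 0.005
```

Reading the output: the unit shown carries significant force and
interaction tuning but no grip tuning; the fitted marginalization
variance shares recover the planted 0.74 / 0.13 / 0.09 / 0.04 split
within a percentage point; and the muscle envelope correlates strongly
with the condition-independent and force components but weakly with the
grip component — the population's force-related latents look like muscle
activity, its grip-related latents do not.

`run_pipeline()` orchestrates all stages from one seed and writes TSV/JSON
reports; `inst/cli/graspdyn.R` exposes the same stages as a command-line
tool (`simulate | behavior | rates | tuning | dpca | emgcorr | run`).

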