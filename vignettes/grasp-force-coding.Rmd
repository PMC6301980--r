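---
title: "Quantifying grip-type and grasp-force coding in neural populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying grip-type and grasp-force coding in neural populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graspdyn)
```

# The task and the analysis problem

`graspdyn` analyses neural population recordings from a delayed grasping
task in which a monkey grasps an instrumented handle with one of two grip
types (whole-hand or precision) at one of three instructed force levels
(low 0--5 N, medium 5--9 N, high 9--12 N). A trial runs through fixation
(400--500 ms), an 800 ms visual cue, a 500--700 ms memory period, a go
signal, reach and grasp, a 1 s force hold, and reward. The scientific
questions the toolchain addresses are: which units are tuned to grip type,
force, or their interaction, and when; how much population variance each
task factor explains; whether the factors can be decoded over time; and how
closely the population's latent signals track forearm muscle activity.

Because no public recording accompanies the task, the package ships a
synthetic-session generator with *planted*, exactly known structure, so
that every stage -- behavioral filtering, signal conditioning, rate
estimation, cluster-based permutation testing, demixed PCA, decoding, and
EMG correlation -- can be validated end to end.

# The composite timeline

All rate-level analyses live on a three-alignment composite timeline: cue
onset (-400 to +1300 ms), handle touch (-500 to +500 ms), and reward onset
(-1000 to +200 ms), in 10 ms analysis bins -- 170 + 100 + 120 = 390 bins.
Spike trains are binned at 1 ms, smoothed with a unit-sum Gaussian kernel
(sigma = 50 ms, truncated at 2.5 sigma and renormalized), scaled to
spikes/s, and read out at the bin centers. Each alignment window is
extended by 2.5 sigma before convolution and cropped afterwards, so kernel
edge effects never reach the analysis bins.

When force is acquired quickly, the tail of the touch-aligned window and
the head of the reward-aligned window show the same moments of real time
twice. Whenever a condition's median acquisition time (AT) is below
500 ms, the duplicated span -- reward-aligned bins earlier than
-(median AT + 500) ms -- is masked for display, and for statistics its
values are replaced by linear interpolation between the flanking bins
(`mask_and_interpolate()`). Linear interpolation is our choice; the
duplicated span is short and flanked by smoothly varying rates, so any
interpolant consistent at the boundaries gives near-identical statistics.
Masking is applied per condition with that condition's own median AT,
which is the finest-grained consistent reading of a per-plot rule.

# Behavioral metrics and exclusions

Reaction time is go to movement onset; movement time is movement onset to
touch; acquisition time is touch to the first force sample at or above the
condition's band minimum, clipped at 0 when the force is already inside
the band at touch (structural for the low band, whose minimum is 0 N).
Trials are excluded when RT > 500 ms, MT > 350 ms, or AT > 1500 ms --
strict inequalities, exactly as printed thresholds are usually applied --
or when more than one handle touch was registered. The early divergence of
force levels is tested per grip type by a one-way ANOVA on the mean force
in the first 100 ms after touch, followed by Tukey--Kramer pairwise
comparisons (the studentized-range procedure with unequal group sizes, via
`TukeyHSD()`). Overshoot fractions count successful trials whose force
exceeds the band maximum anywhere between touch and reward.

A note on AT sign: a sensitive force sensor can register force before the
touch sensors do, which would make a literal band-entry time negative. We
clip AT at 0 and flag the case rather than guess a convention.

# Signal conditioning

Continuous signals are handled by small, composable operators:

* `gaussian_smooth()` -- truncated, unit-sum Gaussian (default sigma
  10 ms, support 2.5 sigma); constants pass unchanged, edges by
  reflection.
* `preprocess_emg()` -- 25--250 Hz Butterworth band-pass (design order 6),
  rectification, Gaussian smoothing (sigma 10 ms), then normalization by
  the mean smoothed activity of the fixation epochs, so 1 equals baseline
  muscle tone.
* `median_highpass()` -- running-median subtraction (window 3.33 ms; at
  30 kHz that rounds to the nearest odd window of 99 samples; edges use
  symmetrically shrinking odd windows).
* `lowpass_filter()` -- 5000 Hz Butterworth (design order 4) for broadband
  data.
* `pca_artifact_cancel()` -- channels are normalized to unit variance and
  decomposed by PCA; dimensions whose loading vector never exceeds 0.36 in
  magnitude are treated as common-mode artifact and subtracted. A waveform
  shared by all 32 channels of an array has loadings 1/sqrt(32) = 0.18 and
  is removed; a waveform confined to one channel has a loading near 1 and
  is kept, so no individual channel can be eliminated.

All filters are applied forward--backward (`filtfilt`), i.e. zero-phase;
this doubles the magnitude-response order of the quoted designs, which we
accept as the standard reading of "non-causal" filtering. Whether the
running median should shrink or pad at the edges is not fixed by
convention; we use shrinking windows because they stay medians of observed
data.

# Cluster-based permutation test of tuning

Per unit, a two-way ANOVA (grip x force) runs at every 10 ms bin of the
overlap-interpolated rates; bins with p < 0.01 form clusters over adjacent
bins, per effect, and cluster F values are summed. The null distribution
comes from 1000 random reassignments of the condition labels, keeping each
shuffle's maximal summed-F cluster per effect; an observed cluster is
significant when its summed F exceeds the 99th percentile of its effect's
null (order statistic `ceiling(0.99 n)`, ties upward, which is the
conservative side). Design choices worth making explicit:

* Type II sums of squares, because trial counts per cell are unequal after
  behavioral exclusions; in the balanced case this coincides with the
  classical decomposition.
* Clusters never span the boundary between alignment segments: adjacency
  across a cut in real time is not meaningful. Interpolated overlap bins
  are ordinary bins and do count as adjacent.
* One set of label permutations is shared by the three effects within a
  unit; sharing changes nothing in distribution for exchangeable labels
  and makes results reproducible from one seed.

The permutation engine is exact in the sense that permuting labels equals
permuting rows, so cell sums for all permutations are computed with one
sparse matrix product, and all four candidate-model fits are read off the
six cell sums; a small compiled kernel sums clusters. One unit with 120
trials, 390 bins and 1000 permutations tests in about half a second on one
core.

`population_fractions()` aggregates per-bin cluster coverage across units;
`preferred_force()` labels each significant force bin with the
grip-averaged argmax force level, breaking exact ties toward the lower
level (logged), so a tie can never inflate apparent high-force preference.

# Marginalization and demixed PCA

A trial-averaged tensor x(unit, force, grip, time) decomposes into eight
averaged terms -- grand mean; pure time, force, grip; time-force,
time-grip, force-grip; and the triple interaction -- each centered over
every index it was averaged over. The terms sum back to the tensor exactly
and are mutually orthogonal on the balanced condition grid, so the
variance shares of the four *combined* marginalizations (condition-
independent = pure time; force = force + time-force; grip = grip +
time-grip; interaction = force-grip + triple) add to one. Each task factor
keeps its time interaction because every signal in this task evolves over
the trial.

`dpca()` fits, per combined marginalization, the reduced-rank ridge
problem min ||X_phi - D F X||^2 + lambda ||D F||^2 with the closed-form
solution: ridge-regress X_phi on the full centered matrix X, then truncate
the fit's rank by SVD. The ridge inverse drops rank-deficient directions,
so lambda = 0 is well defined on noiseless, low-rank data. lambda is
selected on a log-spaced grid including 0 (scaled by the total variance)
by ten rounds of held-out-trial reconstruction: one random trial per unit
and condition is held out, the rest are averaged for training, and the
per-marginalization reconstruction error of the held-out matrix is
accumulated. Components are ordered by explained total variance and capped
at 30 overall. Because the top-k reconstruction is a rank-k linear map,
its cumulative explained variance can never exceed the PCA optimum
(Eckart--Young), a bound the test suite checks.

Two estimator choices deserve justification:

* **Signal-variance shares.** The plug-in variance shares of a noisy trial
  average are inflated by the trial-noise floor, which spreads over
  marginalizations in proportion to their dimensionality. When
  trial-resolved data are available, `dpca()` therefore reports split-half
  shares: trials are split into random halves, each half averaged and
  marginalized, and matching marginalizations cross-multiplied. Noise is
  independent between halves, so its contribution cancels in expectation.
  The plug-in estimate is retained as `marg_shares_plugin`.
* **Decoding axis.** Time-resolved decoding projects pseudo-single-trial
  activity onto the *largest* decoder axis of the factor's
  marginalization. The condition-independent marginalization carries no
  labels and is not decoded. EMG is never passed to dPCA -- with only a
  handful of muscles the decomposition is not meaningful -- and uses the
  marginalization algebra alone.

Decoding uses stratified Monte Carlo leave-group-out cross-validation
(hold out one trial per unit and condition, classify by nearest training
class mean, 100 iterations), with a chance distribution from 100 datasets
whose labels are shuffled within unit. A bin is significant when the
actual accuracy beats *all* shuffle accuracies, and reported intervals
need at least 10 consecutive significant bins.

# EMG--neural correlation

Per muscle, the preprocessed EMG envelope is aligned to the composite
timeline, averaged per condition, and marginalized; the muscles'
marginalizations are averaged. One time shift per population is chosen by
maximizing the squared correlation between the reference condition-
independent component (the largest by default, switchable to the second)
and the EMG condition-independent marginalization over a -500..+500 ms
grid in 10 ms steps (the analysis resolution; the scan granularity is our
choice). That single shift then applies to every (factor, component) pair;
per factor, condition time courses are concatenated in matching order
(three force, two grip) before one squared Pearson correlation. Shifted
ends are masked, not wrapped or zero-padded -- padding biases R^2 toward
zero asymmetrically. Sign convention: positive shift means the neural
signal precedes the muscle signal. Whether muscles should be averaged
before or after marginalization is not determined by the figure the
procedure mirrors; marginalization is linear, so the two orders differ
only for the normalization step, and we marginalize per muscle first.

# What the generator plants, and what it does not emulate

`latent_spec()` plants one latent time course per marginalization with
condition coefficients that average to zero over the factors they vary
with, so each latent contributes variance to exactly one marginalization;
the exact shares implied by the drawn mixing weights are recorded and are
the ground truth for recovery tests. Default target shares are 0.70 /
0.15 / 0.10 / 0.05 (condition-independent / force / grip / interaction),
with an overall modulation scale of 6 spikes/s RMS on baselines of 15--25
spikes/s -- strong but not saturating task modulation. The force latent
separates the low-force condition early and strongly (coefficients
-1.1 / 0.3 / 0.8 before normalization), matching the early low-force
divergence the task produces in force, muscle, and neural signals. Latent
profiles are deliberately flat across the touch-tail / reward-head span so
that alignment duplication cannot move variance between marginalizations;
in real time, earlier alignment windows take precedence and the duplicated
span lands exactly where the masking rule interpolates.

The scheduler reproduces the condition pool (30 trials, 5 copies each,
refill below 25, failures stay in the pool). Trial events are drawn
uniformly over the stated epoch ranges (the least assumption given only
ranges); RT/MT/AT distributions are truncated normals with means and SDs
typical of trained animals, exposed as configuration with no claim of
realism beyond that. The force trace is a logistic rise that first reaches
the band minimum exactly at touch + AT, a plateau inside the band, and an
optional overshoot bump; only AT, band membership, and overshoot matter
downstream, so no biomechanical model is attempted. EMG is a 25--250 Hz
noise carrier amplitude-modulated by a rectified mixture of the condition-
independent and force latents (plus a small grip term), gated off before
the go signal; its variance is dominated by the condition-independent
envelope, as forearm EMG in this task is. Eye-error and execution-failure
rates default to values typical of a well-motivated animal.

Not emulated: spike sorting and waveform synthesis (units are given
directly), eye movements, biomechanics, electrode drift, correlated noise
between units, and non-Poisson spiking statistics. Rates are rectified at
0 before the Poisson draw; at high planted amplitudes rectification leaks
a small amount of variance across marginalizations, which is why the
generator records the clipped mass and the defaults keep it negligible.
Passing tests on these sessions therefore shows the *analysis machinery*
is correct and calibrated -- not that real cortical data satisfy the
generator's assumptions.

# Numerical choices and degenerate inputs

* Truncated kernels are renormalized to unit sum (constants preserved).
* The ridge pseudo-inverse drops directions below `1e-12` of the largest
  eigenvalue; degenerate (all-zero) marginalizations yield zero components
  and are listed in `$dropped`.
* Permutation percentiles use the `ceiling(n q)` order statistic with ties
  upward (conservative).
* Exact ties in preferred force go to the lower level and are logged.
* `exclude_trials()` flags undefined metrics as NA, never 0, and excludes
  on NA success only through the explicit unsuccessful rule.
* Stage seeds are a deterministic integer hash of (global seed, stage
  name), so any stage can be re-run alone and reproduce byte-identical
  output.

# Problem sizes used by the test suite

The default session (100 units, 500 attempted trials) mirrors a realistic
recording day. The validation suite runs smaller configurations chosen for
statistical sufficiency: error-rate calibration uses 1000 simulated null
units (binomial SE ~ 0.3 percentage points at alpha = 1%), detection power
uses 200 units with a five-noise-SD planted effect, dPCA recovery uses 100
units with 20 trials per condition, and decoding calibration uses 100
cross-validation iterations against 100 label shuffles, as in the standard
protocol.

# Known limitations

* The five-dimensional tensor interface assumes trials can be truncated to
  a common per-condition count; how non-simultaneous sessions should be
  stitched into a common trial dimension is left to the user.
* The split-half share estimator assumes noise independent across trials;
  slow drifts shared across trials would survive the cross-product.
* Tukey--Kramer inherits the ANOVA's equal-variance assumption across
  force levels; acquisition-time variability makes early-window force
  variance mildly heteroscedastic.
* On-disk interchange uses TSV and JSON; large binary containers are left
  to the caller's infrastructure.
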