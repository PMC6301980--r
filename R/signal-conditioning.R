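#' Continuous signal container
#'
#' Lightweight container for regularly sampled continuous data (grasp force,
#' EMG, broadband neural signals, firing rates).
#'
#' @param samples numeric vector (or matrix, samples x channels).
#' @param rate sampling rate in Hz; must be positive.
#' @param unit physical unit label, e.g. "N", "uV", "normalized", "spikes/s".
#' @param t0 time of the first sample in ms.
#' @return An object of class `continuous_signal`.
#' @export
continuous_signal <- function(samples, rate, unit = "", t0 = 0) {
  stopifnot(is.numeric(rate), length(rate) == 1, rate > 0)
  if (!all(is.finite(samples))) stop("samples must be finite")
  structure(list(samples = samples, rate = rate, unit = unit, t0 = t0),
            class = "continuous_signal")
}

#' @export
print.continuous_signal <- function(x, ...) {
  n <- if (is.matrix(x$samples)) nrow(x$samples) else length(x$samples)
  ch <- if (is.matrix(x$samples)) ncol(x$samples) else 1L
  cat(sprintf("<continuous_signal> %d samples x %d channel(s) @ %g Hz [%s], t0 = %g ms\n",
              n, ch, x$rate, x$unit, x$t0))
  invisible(x)
}

sig_samples <- function(x) if (inherits(x, "continuous_signal")) x$samples else x

## Truncated, unit-sum Gaussian kernel. `support` is the half-width in
## multiples of sigma (2.5 by default, following the smoothing convention
## "binsize = 2.5 sigma").
gaussian_kernel <- function(sigma_samples, support = 2.5) {
  h <- max(1L, ceiling(support * sigma_samples))
  k <- exp(-0.5 * ((-h:h) / sigma_samples)^2)
  k / sum(k)
}

## Convolve each column with `k` (odd length), edges handled by reflection,
## output length preserved.
convolve_reflect <- function(x, k) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  h <- (length(k) - 1L) %/% 2L
  n <- nrow(x)
  if (h >= n) stop("kernel support longer than signal")
  idx <- c(rev(seq_len(h) + 1L), seq_len(n), n - seq_len(h))
  xp <- x[idx, , drop = FALSE]
  out <- stats::filter(xp, k, method = "convolution", sides = 2)
  out <- out[(h + 1L):(h + n), , drop = FALSE]
  out <- matrix(as.numeric(out), n, ncol(x))
  if (vec) drop(out) else out
}

#' Gaussian smoothing of a continuous signal
#'
#' Convolution with a truncated, renormalized Gaussian kernel. The kernel is
#' cut at `support` multiples of sigma on each side and rescaled to unit sum,
#' so constants pass unchanged. Edges are handled by reflection; output
#' length equals input length. The default sigma of 10 ms is the standard
#' setting for force and EMG envelopes.
#'
#' @param x a [continuous_signal()] or numeric vector/matrix.
#' @param sigma_ms kernel standard deviation in ms (> 0).
#' @param support kernel half-width in multiples of sigma.
#' @param rate sampling rate in Hz; taken from `x` when it is a
#'   `continuous_signal`.
#' @return Same type as `x`.
#' @export
gaussian_smooth <- function(x, sigma_ms = 10, support = 2.5, rate = NULL) {
  if (sigma_ms <= 0) stop("sigma_ms must be > 0")
  if (inherits(x, "continuous_signal")) {
    out <- x
    out$samples <- gaussian_smooth(x$samples, sigma_ms, support, rate = x$rate)
    return(out)
  }
  if (is.null(rate)) stop("rate required for bare numeric input")
  convolve_reflect(x, gaussian_kernel(sigma_ms * rate / 1000, support))
}

## Zero-phase Butterworth via forward-backward filtering. `n` is the design
## order of the underlying one-pass filter; filtfilt squares the magnitude
## response (effective order doubling), which realizes the non-causal filters
## used throughout.
butter_zerophase <- function(x, n, cutoff_hz, rate, type) {
  w <- cutoff_hz / (rate / 2)
  if (any(w <= 0) || any(w >= 1)) stop("cutoff outside (0, Nyquist)")
  flt <- signal::butter(n, w, type = type)
  if (is.matrix(x)) apply(x, 2, function(col) signal::filtfilt(flt, col))
  else signal::filtfilt(flt, x)
}

#' Preprocess raw EMG to a normalized envelope
#'
#' Band-pass filters (25-250 Hz, 6th-order Butterworth, applied zero-phase),
#' rectifies, Gaussian-smooths (sigma = 10 ms), and normalizes by the mean
#' smoothed activity over the per-trial fixation windows, so a value of 1
#' equals baseline muscle tone.
#'
#' @param raw a [continuous_signal()]; `rate` must exceed 500 Hz so the
#'   250 Hz band edge is below Nyquist.
#' @param fixation_windows two-column matrix (start, end in ms, absolute time)
#'   of fixation epochs used for normalization.
#' @param band two-element numeric band edges in Hz.
#' @param order Butterworth design order of the band-pass.
#' @param sigma_ms envelope smoothing sigma in ms.
#' @return A `continuous_signal` with unit "normalized".
#' @export
preprocess_emg <- function(raw, fixation_windows, band = c(25, 250),
                           order = 6, sigma_ms = 10) {
  stopifnot(inherits(raw, "continuous_signal"))
  if (raw$rate <= 2 * band[2]) stop("sampling rate too low for band edge")
  ## a band-pass of design order `order` is built from an order/2 prototype
  filt <- butter_zerophase(raw$samples, n = order / 2, cutoff_hz = band,
                           rate = raw$rate, type = "pass")
  env <- gaussian_smooth(abs(filt), sigma_ms, rate = raw$rate)
  fixation_windows <- as.matrix(fixation_windows)
  fixation_windows <- fixation_windows[complete.cases(fixation_windows), ,
                                       drop = FALSE]
  idx <- unlist(lapply(seq_len(nrow(fixation_windows)), function(i) {
    a <- max(1L, floor((fixation_windows[i, 1] - raw$t0) * raw$rate / 1000) + 1L)
    b <- min(NROW(env), floor((fixation_windows[i, 2] - raw$t0) * raw$rate / 1000) + 1L)
    if (b >= a) seq.int(a, b) else integer(0)
  }))
  if (length(idx) == 0) stop("no samples in fixation windows")
  base <- if (is.matrix(env)) colMeans(env[idx, , drop = FALSE]) else mean(env[idx])
  if (any(base == 0)) stop("fixation-epoch mean is zero; cannot normalize")
  out <- raw
  out$samples <- if (is.matrix(env)) sweep(env, 2, base, "/") else env / base
  out$unit <- "normalized"
  out
}

#' Median high-pass filter for broadband signals
#'
#' Subtracts a running median (default window 3.33 ms) from the signal,
#' removing slow baseline components while preserving fast transients such as
#' spike waveforms. The window is rounded to the nearest odd number of
#' samples (ties downward); at 30 kHz, 3.33 ms gives a 99-sample window.
#' Edges use symmetrically shrinking odd windows.
#'
#' @param x a [continuous_signal()] or numeric vector with `rate` given.
#' @param window_ms median window length in ms.
#' @param rate sampling rate in Hz for bare numeric input.
#' @return Same type as `x`.
#' @export
median_highpass <- function(x, window_ms = 3.33, rate = NULL) {
  if (inherits(x, "continuous_signal")) {
    out <- x
    out$samples <- median_highpass(x$samples, window_ms, rate = x$rate)
    return(out)
  }
  if (is.null(rate)) stop("rate required for bare numeric input")
  k <- round(window_ms * rate / 1000)
  k <- if (k %% 2 == 1) k else k - 1L   # nearest odd, ties downward
  if (k < 3) stop("window must span at least 3 samples")
  n <- length(x)
  if (k > n) stop("window longer than signal")
  med <- as.numeric(stats::runmed(x, k, endrule = "keep"))
  h <- (k - 1L) %/% 2L
  for (i in seq_len(h)) {          # shrinking symmetric odd windows at edges
    med[i] <- median(x[1:(2 * i - 1)])
    med[n - i + 1L] <- median(x[(n - 2 * i + 2):n])
  }
  x - med
}

#' Low-pass filter for broadband signals
#'
#' Zero-phase Butterworth low-pass (default 5000 Hz, design order 4) applied
#' after median high-pass filtering in the broadband conditioning chain.
#'
#' @inheritParams median_highpass
#' @param cutoff_hz corner frequency in Hz.
#' @param order Butterworth design order.
#' @export
lowpass_filter <- function(x, cutoff_hz = 5000, order = 4, rate = NULL) {
  if (inherits(x, "continuous_signal")) {
    out <- x
    out$samples <- lowpass_filter(x$samples, cutoff_hz, order, rate = x$rate)
    return(out)
  }
  if (is.null(rate)) stop("rate required for bare numeric input")
  butter_zerophase(x, n = order, cutoff_hz = cutoff_hz, rate = rate, type = "low")
}

#' PCA artifact cancellation across electrode channels
#'
#' Removes common-mode artifacts shared across the channels of an array.
#' Channels are normalized to zero mean and unit variance, decomposed by PCA,
#' and every principal dimension whose loading vector has no coefficient
#' exceeding `coeff_threshold` in absolute value is treated as a common
#' artifact and subtracted. Dimensions with any loading above the threshold
#' carry channel-specific signal and are retained, which guarantees that no
#' individual channel is eliminated: a waveform confined to one channel has a
#' loading near 1 on that channel and survives, whereas a waveform shared
#' equally by m channels has loadings 1/sqrt(m) and is removed once
#' 1/sqrt(m) <= threshold.
#'
#' @param channels samples x channels numeric matrix or a multi-channel
#'   [continuous_signal()]; at least 2 channels.
#' @param coeff_threshold loading magnitude above which a dimension is kept.
#' @return Object of class `pca_artifact`: list with `cleaned` (same shape as
#'   input), `removed` (indices of subtracted dimensions), and `loadings`.
#' @export
pca_artifact_cancel <- function(channels, coeff_threshold = 0.36) {
  sig <- inherits(channels, "continuous_signal")
  X <- if (sig) channels$samples else channels
  if (!is.matrix(X) || ncol(X) < 2) stop("need at least 2 channels")
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, s, "/")
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
  artifact <- which(apply(abs(pc$rotation), 2, max) <= coeff_threshold)
  if (length(artifact)) {
    Xs <- Xs - pc$x[, artifact, drop = FALSE] %*%
      t(pc$rotation[, artifact, drop = FALSE])
  }
  cleaned <- sweep(sweep(Xs, 2, s, "*"), 2, mu, "+")
  if (sig) {
    out <- channels
    out$samples <- cleaned
    cleaned <- out
  }
  structure(list(cleaned = cleaned, removed = artifact,
                 loadings = pc$rotation, threshold = coeff_threshold),
            class = "pca_artifact")
}

#' @export
print.pca_artifact <- function(x, ...) {
  cat(sprintf("PCA artifact cancellation: %d of %d dimensions removed (threshold %.2f)\n",
              length(x$removed), ncol(x$loadings), x$threshold))
  invisible(x)
}
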