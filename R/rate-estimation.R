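## 1-ms position (within the concatenated 1-ms composite grid) of each
## 10-ms analysis bin center.
bin_center_indices <- function(spec = alignment_spec()) {
  offs <- 0L
  idx <- integer(0)
  for (w in spec$windows) {
    centers <- seq(w[1] + spec$bin_ms / 2, w[2] - spec$bin_ms / 2, by = spec$bin_ms)
    idx <- c(idx, offs + (centers - w[1]) + 0.5 + 0.5)  # integer positions
    offs <- offs + diff(w)
  }
  as.integer(idx)
}

## 10-ms bin-center positions within each 1-ms segment grid.
seg_center_idx <- function(spec) {
  lapply(spec$windows, function(w) {
    centers <- seq(w[1] + spec$bin_ms / 2, w[2] - spec$bin_ms / 2,
                   by = spec$bin_ms)
    as.integer(centers - w[1] + 1)
  })
}

## Sparse operator: smoothed value at each bin center of a padded 1-ms
## segment (data includes `pad` extra samples on both sides).
decim_matrix_padded <- function(len, centers, kern, pad) {
  h <- (length(kern) - 1L) %/% 2L
  stopifnot(pad >= h)
  i <- rep(seq_along(centers), each = length(kern))
  j <- rep(centers + pad, each = length(kern)) + (-h):h
  Matrix::sparseMatrix(i = i, j = j, x = rep(kern, length(centers)),
                       dims = c(length(centers), len + 2L * pad))
}

## Same for unpadded data, reflecting the kernel at the segment edges
## (duplicated entries are summed by the sparse constructor).
decim_matrix_reflect <- function(len, centers, kern) {
  h <- (length(kern) - 1L) %/% 2L
  i <- rep(seq_along(centers), each = length(kern))
  j <- rep(centers, each = length(kern)) + (-h):h
  j[j < 1] <- 2L - j[j < 1]
  j[j > len] <- 2L * len - j[j > len]
  Matrix::sparseMatrix(i = i, j = j, x = rep(kern, length(centers)),
                       dims = c(length(centers), len))
}

## Block-diagonal smoother over the whole composite 1-ms grid.
composite_smoother <- function(spec, kern = gaussian_kernel(spec$sigma_ms)) {
  lens <- vapply(spec$windows, diff, 0)
  cidx <- seg_center_idx(spec)
  Matrix::bdiag(lapply(seq_along(lens), function(si)
    decim_matrix_reflect(lens[si], cidx[[si]], kern)))
}

#' Smoothed firing rates on the composite timeline
#'
#' Converts spike times to trial-resolved firing rates: per trial and
#' alignment window, the 1 ms binary spike train is convolved with a
#' unit-sum Gaussian kernel (sigma = 50 ms) and scaled to spikes/s; each
#' window is extended by 2.5 sigma before convolution and cropped afterwards
#' so smoothing edge effects stay outside the analysis windows. The three
#' aligned segments are concatenated and decimated at the 10 ms bin centers,
#' giving 390 analysis bins per trial.
#'
#' Only successful trials with all three alignment events are included;
#' dropped trials are recorded in the `dropped` element.
#'
#' @param spikes list of per-unit spike time vectors (absolute ms).
#' @param trial_table trial table (see [simulate_session()]).
#' @param spec an [alignment_spec()].
#' @return Object of class `rate_tensor`: list with `rates`
#'   (unit x trial x bin array, spikes/s), `trials` (labels of retained
#'   trials), `timeline`, `spec`, `dropped`.
#' @export
spikes_to_rates <- function(spikes, trial_table, spec = alignment_spec()) {
  anchors <- c(cue = "t_cue_on", touch = "t_touch", reward = "t_reward")
  have_events <- complete.cases(trial_table[, anchors])
  keep <- trial_table$success & have_events
  dropped <- trial_table$trial_id[!keep]
  tt <- trial_table[keep, , drop = FALSE]
  nu <- length(spikes); ntr <- nrow(tt)
  if (ntr == 0) stop("no retained trials")
  kern <- gaussian_kernel(spec$sigma_ms)
  pad <- (length(kern) - 1L) %/% 2L
  cidx <- seg_center_idx(spec)
  nb <- sum(lengths(cidx))
  rates <- array(0, dim = c(nu, ntr, nb))
  lens <- vapply(spec$windows, diff, 0)
  Ks <- lapply(seq_along(lens), function(si)
    decim_matrix_padded(lens[si], cidx[[si]], kern, pad))
  bin_off <- c(0L, cumsum(lengths(cidx)))
  for (u in seq_len(nu)) {
    sp <- sort(spikes[[u]])
    for (si in seq_along(spec$windows)) {
      w <- spec$windows[[si]]
      evts <- tt[[anchors[si]]]
      len <- lens[si]
      counts <- matrix(0, len + 2L * pad, ntr)
      lo <- evts + w[1] - pad
      a <- findInterval(lo - 1e-9, sp) + 1L
      b <- findInterval(evts + w[2] + pad - 1e-9, sp)
      for (i in seq_len(ntr)) {
        if (b[i] >= a[i]) {
          bins <- floor(sp[a[i]:b[i]] - lo[i]) + 1L
          counts[, i] <- tabulate(bins, nbins = len + 2L * pad)
        }
      }
      sm <- as.matrix(Ks[[si]] %*% counts) * 1000
      rates[u, , bin_off[si] + seq_along(cidx[[si]])] <- t(sm)
    }
  }
  structure(list(rates = rates,
                 trials = tt[, c("trial_id", "condition", "grip", "force")],
                 timeline = composite_timeline(spec), spec = spec,
                 dropped = dropped),
            class = "rate_tensor")
}

#' @export
print.rate_tensor <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("<rate_tensor> %d units x %d trials x %d bins (%d trials dropped)\n",
              d[1], d[2], d[3], length(x$dropped)))
  print(table(x$trials$condition))
  invisible(x)
}

#' Trial-averaged rate tensor
#'
#' Averages a trial-resolved [spikes_to_rates()] tensor within condition,
#' returning the 4-D array (unit x force x grip x time) used by
#' [marginalize()] and [dpca()].
#'
#' @param x a `rate_tensor`.
#' @return 4-D array with dimnames on the force and grip axes; attribute
#'   `n_trials` gives per-condition trial counts.
#' @export
trial_average <- function(x) {
  stopifnot(inherits(x, "rate_tensor"))
  d <- dim(x$rates)
  out <- array(NA_real_, dim = c(d[1], 3, 2, d[3]),
               dimnames = list(NULL, FORCES, GRIPS, NULL))
  counts <- matrix(0L, 3, 2, dimnames = list(FORCES, GRIPS))
  for (f in FORCES) for (g in GRIPS) {
    sel <- x$trials$force == f & x$trials$grip == g
    if (!any(sel)) stop("empty condition cell: ", g, ".", f)
    counts[f, g] <- sum(sel)
    out[, match(f, FORCES), match(g, GRIPS), ] <-
      apply(x$rates[, sel, , drop = FALSE], c(1, 3), mean)
  }
  attr(out, "n_trials") <- counts
  out
}

#' Stack a trial-resolved tensor into the 5-D dPCA input
#'
#' Rearranges a `rate_tensor` into the array (unit x force x grip x time x
#' trial) expected by [dpca()] and [decode_over_time()], truncating every
#' condition to the smallest per-condition trial count (trials are taken in
#' session order).
#'
#' @param x a `rate_tensor`.
#' @return 5-D array.
#' @export
as_tensor5d <- function(x) {
  stopifnot(inherits(x, "rate_tensor"))
  d <- dim(x$rates)
  n_min <- min(table(factor(x$trials$condition,
                            levels = task_conditions()$condition)))
  if (n_min == 0) stop("empty condition cell")
  out <- array(NA_real_, dim = c(d[1], 3, 2, d[3], n_min),
               dimnames = list(NULL, FORCES, GRIPS, NULL, NULL))
  for (f in 1:3) for (g in 1:2) {
    sel <- which(x$trials$force == FORCES[f] & x$trials$grip == GRIPS[g])[1:n_min]
    out[, f, g, , ] <- aperm(x$rates[, sel, , drop = FALSE], c(1, 3, 2))
  }
  out
}

#' Mask and interpolate the touch/reward alignment overlap
#'
#' When the median acquisition time (AT) of a condition is below 500 ms, the
#' head of the reward-aligned segment duplicates real time already shown at
#' the tail of the touch-aligned segment. Those bins -- reward-aligned
#' centers earlier than -(median AT + 500) ms -- are flagged in a display
#' mask, and for statistical analysis their values are replaced by linear
#' interpolation between the flanking unmasked bins. With median AT >= 500 ms
#' the mask is empty. Masking is applied per condition with that condition's
#' median AT.
#'
#' @param x a `rate_tensor` (trial-resolved) or 4-D trial-averaged array.
#' @param median_at median acquisition time in ms: a single number or a
#'   named vector over conditions (`grip.force` labels).
#' @param timeline a [composite_timeline()]; taken from `x` when it is a
#'   `rate_tensor`.
#' @return Same type as `x` with masked bins interpolated; the display mask
#'   is attached as attribute `mask` (bins x conditions logical matrix).
#' @export
mask_and_interpolate <- function(x, median_at, timeline = NULL) {
  conds <- task_conditions()$condition
  at <- if (length(median_at) == 1) setNames(rep(median_at, 6), conds)
        else median_at[conds]
  if (inherits(x, "rate_tensor")) {
    tl <- x$timeline
    mask <- vapply(conds, function(cc) {
      m <- logical(nrow(tl)); m[overlap_bins(tl, at[[cc]])] <- TRUE; m
    }, logical(nrow(tl)))
    for (cc in conds) {
      bins <- which(mask[, cc])
      if (!length(bins)) next
      rows <- which(x$trials$condition == cc)
      if (!length(rows)) next
      x$rates[, rows, ] <- interp_span(x$rates[, rows, , drop = FALSE], bins)
    }
    attr(x, "mask") <- mask
    return(x)
  }
  stopifnot(length(dim(x)) == 4)
  if (is.null(timeline)) timeline <- composite_timeline()
  mask <- vapply(conds, function(cc) {
    m <- logical(nrow(timeline)); m[overlap_bins(timeline, at[[cc]])] <- TRUE; m
  }, logical(nrow(timeline)))
  for (f in 1:3) for (g in 1:2) {
    cc <- condition_of(GRIPS[g], FORCES[f])
    bins <- which(mask[, cc])
    if (!length(bins)) next
    slab <- x[, f, g, , drop = FALSE]
    dim(slab) <- c(dim(x)[1], 1, dim(x)[4])
    x[, f, g, ] <- interp_span(slab, bins)[, 1, ]
  }
  attr(x, "mask") <- mask
  x
}

## Replace the contiguous bin span `bins` along the last axis of a
## (unit x trial x bin) array by linear interpolation between the flanking
## bins.
interp_span <- function(arr, bins) {
  nb <- dim(arr)[3]
  lo <- min(bins) - 1L; hi <- max(bins) + 1L
  if (lo < 1 || hi > nb) stop("masked span has no flanking bins")
  w <- (bins - lo) / (hi - lo)
  for (k in seq_along(bins))
    arr[, , bins[k]] <- (1 - w[k]) * arr[, , lo] + w[k] * arr[, , hi]
  arr
}

#' Median acquisition time per condition
#'
#' Convenience wrapper: median of `t_acquired - t_touch` over successful
#' trials, per condition, for use with [mask_and_interpolate()].
#'
#' @param trial_table trial table.
#' @return Named numeric vector over the six conditions (NA when a condition
#'   has no successful trials).
#' @export
median_at_per_condition <- function(trial_table) {
  conds <- task_conditions()$condition
  vapply(setNames(conds, conds), function(cc) {
    sel <- trial_table$condition == cc & trial_table$success &
      !is.na(trial_table$t_acquired)
    if (!any(sel)) return(NA_real_)
    median(trial_table$t_acquired[sel] - trial_table$t_touch[sel])
  }, 0)
}
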