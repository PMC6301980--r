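#' Time-shift search specification
#'
#' @param range_ms maximum shift magnitude; the grid spans -range_ms to
#'   +range_ms.
#' @param step_ms grid step (the 10 ms analysis bin by default).
#' @param ref_component which condition-independent component anchors the
#'   shift (1 = largest; 2 available for populations whose largest
#'   component is poorly muscle-correlated).
#' @return Object of class `shift_spec`.
#' @export
shift_spec <- function(range_ms = 500, step_ms = 10, ref_component = 1) {
  stopifnot(range_ms %% step_ms == 0, ref_component %in% 1:2)
  structure(list(range_ms = range_ms, step_ms = step_ms,
                 shifts = seq(-range_ms, range_ms, by = step_ms),
                 ref_component = ref_component),
            class = "shift_spec")
}

## Shift series b by `k` bins relative to a (positive k: a leads b, i.e. a
## at bin t is paired with b at bin t + k), masking the non-overlapping
## ends. Works per column for multi-condition series.
shifted_pair <- function(a, b, k) {
  n <- nrow(a)
  if (k >= 0) list(a = a[seq_len(n - k), , drop = FALSE],
                   b = b[seq_len(n - k) + k, , drop = FALSE])
  else list(a = a[seq_len(n + k) - k, , drop = FALSE],
            b = b[seq_len(n + k), , drop = FALSE])
}

#' Squared correlation over a grid of time shifts
#'
#' For each shift on the grid, pairs the two series with masked (not
#' wrapped) ends -- shifting each condition's time course separately when
#' the series are matrices -- and computes the squared Pearson correlation
#' over the concatenated overlap. Positive shifts mean the first series
#' (neural, by convention) leads the second (muscle).
#'
#' @param a,b numeric vectors or time x condition matrices on the same
#'   timeline.
#' @param spec a [shift_spec()].
#' @return Data frame with columns `shift` (ms) and `r2`.
#' @export
shift_scan <- function(a, b, spec = shift_spec()) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b), ncol(a) == ncol(b))
  if (sd(as.vector(a)) == 0 || sd(as.vector(b)) == 0)
    stop("zero-variance series")
  bins <- spec$shifts / attr_step(spec)
  n <- nrow(a)
  if (max(abs(bins)) > n / 2) stop("shift range leaves < 50% overlap")
  r2 <- vapply(bins, function(k) {
    p <- shifted_pair(a, b, as.integer(k))
    cor(as.vector(p$a), as.vector(p$b))^2
  }, 0)
  data.frame(shift = spec$shifts, r2 = r2)
}

attr_step <- function(spec) spec$step_ms

## Condition time courses of a model component: time x 3 (force, averaged
## over grips), time x 2 (grip, averaged over forces), or time x 1
## (condition-independent, averaged over all conditions).
component_courses <- function(scores_k, factor) {
  ## scores_k: force x grip x time
  switch(factor,
         condition_independent = matrix(apply(scores_k, 3, mean), ncol = 1),
         force = t(apply(scores_k, c(1, 3), mean)),
         grip = t(apply(scores_k, c(2, 3), mean)))
}

## Same for an EMG marginalization_set (unit dim of length 1).
emg_courses <- function(mset, factor) {
  m <- mset$combined[[factor]]            # 1 x force x grip x time
  component_courses(array(m[1, , , ], dim(m)[2:4]), factor)
}

#' Align a continuous signal to the composite timeline
#'
#' Samples a (preprocessed) continuous signal -- EMG envelope or force --
#' at the 10 ms bin centers of the three alignment windows of every
#' retained trial and averages within condition, yielding the 4-D tensor
#' (1 x force x grip x time) consumed by [marginalize()].
#'
#' @param x a [continuous_signal()].
#' @param trial_table trial table; only successful trials with all three
#'   alignment events are used.
#' @param spec an [alignment_spec()].
#' @return 4-D array (1 x force x grip x bins).
#' @export
signal_to_tensor <- function(x, trial_table, spec = alignment_spec()) {
  stopifnot(inherits(x, "continuous_signal"))
  tl <- composite_timeline(spec)
  anchors <- c(cue = "t_cue_on", touch = "t_touch", reward = "t_reward")
  keep <- trial_table$success & complete.cases(trial_table[, anchors])
  tt <- trial_table[keep, , drop = FALSE]
  if (!nrow(tt)) stop("no retained trials")
  nb <- nrow(tl)
  out <- array(0, dim = c(1, 3, 2, nb), dimnames = list(NULL, FORCES, GRIPS, NULL))
  nsm <- length(x$samples)
  for (f in 1:3) for (g in 1:2) {
    sel <- which(tt$force == FORCES[f] & tt$grip == GRIPS[g])
    if (!length(sel)) stop("empty condition cell")
    acc <- numeric(nb)
    for (i in sel) {
      tms <- numeric(nb)
      for (si in names(anchors))
        tms[tl$segment == si] <- tt[[anchors[[si]]]][i] +
          tl$center[tl$segment == si]
      idx <- pmin(pmax(round((tms - x$t0) * x$rate / 1000) + 1, 1), nsm)
      acc <- acc + x$samples[idx]
    }
    out[1, f, g, ] <- acc / length(sel)
  }
  out
}

#' Correlate EMG marginalizations with demixed components
#'
#' Chooses one time shift per population by maximizing the squared
#' correlation between the reference condition-independent component and
#' the EMG condition-independent marginalization, then applies that single
#' shift to every (factor, component) pair. For each factor the condition
#' time courses are concatenated in matching order (three force conditions,
#' two grip conditions) before computing one squared Pearson correlation
#' per pair. Positive shifts mean the neural signal precedes the muscle
#' signal.
#'
#' @param emg_margs list of `marginalization_set` objects, one per muscle
#'   (they are averaged), or a single set.
#' @param model a fitted [dpca()] object on the same composite timeline.
#' @param spec a [shift_spec()].
#' @param n_components number of leading components per factor to
#'   correlate.
#' @return Object of class `emg_correlation`: `shift` (ms), `r2` (factor x
#'   component matrix), `scan` (reference R^2 per shift).
#' @export
correlate_components <- function(emg_margs, model, spec = shift_spec(),
                                 n_components = 2) {
  if (inherits(emg_margs, "marginalization_set")) emg_margs <- list(emg_margs)
  nb <- dim(model$scores)[4]
  if (dim(emg_margs[[1]]$combined[[1]])[4] != nb)
    stop("EMG and model are on different timelines")
  ## average the muscles' marginalizations
  avg <- emg_margs[[1]]
  if (length(emg_margs) > 1) {
    for (m in names(avg$combined)) {
      for (j in 2:length(emg_margs))
        avg$combined[[m]] <- avg$combined[[m]] + emg_margs[[j]]$combined[[m]]
      avg$combined[[m]] <- avg$combined[[m]] / length(emg_margs)
    }
  }
  factors <- c("condition_independent", "force", "grip")
  comp_idx <- lapply(factors, function(f) which(model$marg == f))
  names(comp_idx) <- factors
  ref_k <- comp_idx$condition_independent[spec$ref_component]
  if (is.na(ref_k)) stop("reference condition-independent component not available")
  ref_neural <- component_courses(array(model$scores[ref_k, , , ],
                                        dim(model$scores)[2:4]),
                                  "condition_independent")
  ref_emg <- emg_courses(avg, "condition_independent")
  scan <- shift_scan(ref_neural, ref_emg, spec)
  shift <- scan$shift[which.max(scan$r2)]
  kbin <- as.integer(shift / spec$step_ms)

  r2 <- matrix(NA_real_, length(factors), n_components,
               dimnames = list(factors, paste0("dPC", seq_len(n_components))))
  for (f in factors) {
    for (j in seq_len(n_components)) {
      k <- comp_idx[[f]][j]
      if (is.na(k)) next
      neural <- component_courses(array(model$scores[k, , , ],
                                        dim(model$scores)[2:4]), f)
      emg <- emg_courses(avg, f)
      p <- shifted_pair(neural, emg, kbin)
      r2[f, j] <- cor(as.vector(p$a), as.vector(p$b))^2
    }
  }
  structure(list(shift = shift, r2 = r2, scan = scan, spec = spec),
            class = "emg_correlation")
}

#' @export
print.emg_correlation <- function(x, ...) {
  cat(sprintf("EMG-neural correlation: chosen shift %+d ms (positive = neural leads)\n",
              x$shift))
  print(round(x$r2, 3))
  invisible(x)
}
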