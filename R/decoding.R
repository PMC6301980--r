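#' Assemble pseudo-single-trial draws
#'
#' Samples, for one condition, one trial per unit per fold without
#' replacement within each unit's pool (pools are replenished once
#' exhausted, so a trial is used at most once per sweep through the pool).
#' For simultaneously recorded data, pass `simultaneous = TRUE` to use the
#' same trial index for every unit, so the pseudo-trial equals the actual
#' population trial.
#'
#' @param pools list of per-unit integer vectors of available trial
#'   indices.
#' @param n_folds number of folds to draw.
#' @param simultaneous logical; all units share one pool (the first).
#' @return unit x fold integer matrix of trial indices.
#' @export
make_pseudo_trials <- function(pools, n_folds, simultaneous = FALSE) {
  nu <- length(pools)
  out <- matrix(0L, nu, n_folds)
  if (simultaneous) {
    draw <- sample(pools[[1]])
    while (length(draw) < n_folds) draw <- c(draw, sample(pools[[1]]))
    out[] <- rep(draw[seq_len(n_folds)], each = nu)
    return(out)
  }
  for (u in seq_len(nu)) {
    draw <- sample(pools[[u]])
    while (length(draw) < n_folds) draw <- c(draw, sample(pools[[u]]))
    out[u, ] <- draw[seq_len(n_folds)]
  }
  out
}

#' Time-resolved decoding of a task factor from population activity
#'
#' Projects pseudo-single-trial population activity onto the leading
#' decoder axis of the factor's marginalization and classifies each time
#' bin by the nearest training class mean, using stratified Monte Carlo
#' leave-group-out cross-validation: in every iteration one trial per unit
#' and condition is held out as the test group and the class means are
#' computed from the remaining trials. A Monte Carlo chance distribution is
#' built by repeating the full procedure on `n_shuffles` datasets with
#' condition labels shuffled within each unit; a bin is significant when
#' the actual accuracy exceeds all shuffle accuracies, and reported
#' significance intervals require at least `consecutive_bins` consecutive
#' significant bins.
#'
#' @param model a fitted [dpca()] object (supplies the decoder axis), or a
#'   numeric decoder vector of length `dim(x5)[1]`.
#' @param x5 5-D tensor (unit x force x grip x time x trial), complete (no
#'   NA).
#' @param factor "grip" (chance 1/2) or "force" (chance 1/3); the
#'   condition-independent marginalization carries no labels to decode.
#' @param cv_iterations cross-validation iterations per dataset.
#' @param n_shuffles shuffled datasets for the chance distribution.
#' @param consecutive_bins run length required to report an interval.
#' @param seed integer seed.
#' @return Object of class `decoding_result`: `accuracy` (per bin),
#'   `shuffle_accuracy` (n_shuffles x bins), `significant` (per bin),
#'   `intervals` (data.frame start/end), `chance`, `factor`.
#' @export
decode_over_time <- function(model, x5, factor = c("grip", "force"),
                             cv_iterations = 100, n_shuffles = 100,
                             consecutive_bins = 10, seed = NULL) {
  factor <- match.arg(factor)
  if (!is.null(seed)) set.seed(seed)
  if (anyNA(x5)) stop("decoding requires a complete trial tensor")
  d <- dim(x5)
  stopifnot(length(d) == 5)
  N <- d[1]; Tb <- d[4]; n <- d[5]
  if (n < 2) stop("need >= 2 trials per condition")
  axis <- if (is.numeric(model)) model else {
    idx <- which(model$marg == factor)
    if (!length(idx)) stop("model has no ", factor, " component")
    drop(model$decoder[idx[1], ])
  }
  ## projected activity, rows = (unit fastest, force, grip, trial), cols = bins
  Q <- x5 * axis                              # recycles along the unit dim
  Q <- aperm(Q, c(1, 2, 3, 5, 4))
  n_rows <- N * 6 * n
  dim(Q) <- c(n_rows, Tb)
  u_of <- rep_len(seq_len(N), n_rows)
  c_of <- rep(rep(1:6, each = N), times = n)  # condition = f + 3 (g - 1)
  cls_of_cond <- if (factor == "grip") rep(1:2, each = 3) else rep(1:3, 2)
  n_cls <- max(cls_of_cond)
  cls_sizes <- as.vector(table(cls_of_cond))
  it_idx6 <- rep(seq_len(cv_iterations), each = 6)

  decode_dataset <- function(lab) {
    S <- rowsum(Q, lab)                       # 6 x Tb condition sums
    ## pools: rows of each (unit, condition) group, n rows each
    pools <- split(seq_len(n_rows), (u_of - 1L) * 6L + lab)
    pool_mat <- matrix(unlist(pools, use.names = FALSE), n, N * 6)
    picks <- ceiling(runif(N * 6 * cv_iterations) * n)
    sel <- pool_mat[cbind(picks, rep(seq_len(N * 6), times = cv_iterations))]
    grp_c <- ((seq_len(N * 6) - 1L) %% 6L) + 1L
    ii <- rep((seq_len(cv_iterations) - 1L) * 6L, each = N * 6) +
      rep(grp_c, cv_iterations)
    Msel <- Matrix::sparseMatrix(i = ii, j = sel, x = 1,
                                 dims = c(6L * cv_iterations, n_rows))
    test <- as.matrix(Msel %*% Q)             # (6 iters) x Tb pseudo-trials
    train_mean <- (S[rep(1:6, cv_iterations), , drop = FALSE] - test) / (n - 1)
    cls_grp <- rep((seq_len(cv_iterations) - 1L) * n_cls, each = 6) + cls_of_cond
    cls_mean <- rowsum(train_mean, cls_grp) /
      rep(cls_sizes, cv_iterations)           # (n_cls iters) x Tb
    best <- matrix(Inf, 6L * cv_iterations, Tb)
    pred <- matrix(1L, 6L * cv_iterations, Tb)
    for (k in seq_len(n_cls)) {
      rows_k <- (it_idx6 - 1L) * n_cls + k
      dk <- abs(test - cls_mean[rows_k, , drop = FALSE])
      upd <- dk < best
      best[upd] <- dk[upd]
      pred[upd] <- k
    }
    truth <- cls_of_cond[rep(1:6, cv_iterations)]
    colMeans(pred == truth)
  }

  acc <- decode_dataset(c_of)
  shuf <- matrix(0, n_shuffles, Tb)
  for (s in seq_len(n_shuffles)) {
    lab_s <- integer(n_rows)
    for (u in seq_len(N)) {
      rows_u <- which(u_of == u)
      lab_s[rows_u] <- sample(c_of[rows_u])
    }
    shuf[s, ] <- decode_dataset(lab_s)
  }
  sig <- if (n_shuffles > 0) acc > apply(shuf, 2, max) else acc > 1
  intervals <- significant_intervals(sig, consecutive_bins)
  structure(list(accuracy = acc, shuffle_accuracy = shuf, significant = sig,
                 intervals = intervals, chance = 1 / n_cls, factor = factor,
                 consecutive_bins = consecutive_bins),
            class = "decoding_result")
}

#' Run-length filtered significance intervals
#'
#' Contiguous runs of per-bin significance that reach the minimum run
#' length; shorter runs are not reported.
#'
#' @param sig logical vector.
#' @param min_len minimum run length (10 bins by default).
#' @return Data frame with columns start, end (empty when no run
#'   qualifies).
#' @export
significant_intervals <- function(sig, min_len = 10) {
  r <- rle(as.logical(sig))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Decoding of %s: mean accuracy %.3f (chance %.3f), %d significant bin(s)\n",
              x$factor, mean(x$accuracy), x$chance, sum(x$significant)))
  if (nrow(x$intervals))
    cat("intervals (>= ", x$consecutive_bins, " bins): ",
        paste(sprintf("[%d, %d]", x$intervals$start, x$intervals$end),
              collapse = " "), "\n", sep = "")
  invisible(x)
}
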