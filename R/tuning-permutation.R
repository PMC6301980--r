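#' Configuration of the cluster-based permutation tuning test
#'
#' Defaults follow the standard protocol: two-way ANOVA in 10 ms steps,
#' cluster-forming threshold p < 0.01, 1000 label permutations, and
#' significance at the 99th percentile of the per-effect max-cluster null
#' distribution (alpha = 0.01).
#'
#' @param cluster_forming_p pointwise p threshold that forms clusters.
#' @param n_permutations number of label shuffles.
#' @param alpha family-wise level; the null percentile is 100 (1 - alpha).
#' @param rng_seed optional integer seed.
#' @return Object of class `cluster_test_config`.
#' @export
cluster_test_config <- function(cluster_forming_p = 0.01,
                                n_permutations = 1000, alpha = 0.01,
                                rng_seed = NULL) {
  structure(list(cluster_forming_p = cluster_forming_p,
                 n_permutations = n_permutations, alpha = alpha,
                 percentile = 100 * (1 - alpha), rng_seed = rng_seed),
            class = "cluster_test_config")
}

EFFECTS <- c("grip", "force", "interaction")

## Design bookkeeping in the 6-cell space (grip x force). Each candidate
## model's column space is spanned by the cell indicators, so fitted sums of
## squares are computed from permuted cell sums; Type II sums of squares:
## each main effect is adjusted for the other main effect, the interaction
## for both.
cell_designs <- function() {
  cells <- expand.grid(grip = factor(GRIPS, levels = GRIPS),
                       force = factor(FORCES, levels = FORCES))
  list(cells = cells,
       B = list(g = stats::model.matrix(~grip, cells),
                f = stats::model.matrix(~force, cells),
                gf = stats::model.matrix(~grip + force, cells),
                full = stats::model.matrix(~grip * force, cells)))
}

#' Cluster-based permutation test of grip/force/interaction tuning
#'
#' For one unit, applies a two-way ANOVA (grip x force, Type II sums of
#' squares for unbalanced cells) to each 10 ms bin of the trial-resolved,
#' overlap-interpolated firing rates. Adjacent bins with p below the
#' cluster-forming threshold are combined into clusters (never across
#' alignment-segment boundaries) and their F values summed, separately for
#' the grip main effect, force main effect, and interaction. The null
#' distribution is built from `n_permutations` random reassignments of the
#' condition labels -- shared across the three effects -- keeping each
#' shuffle's maximal summed-F cluster per effect; an observed cluster is
#' significant when its summed F exceeds the 99th percentile of its
#' effect's null distribution (order statistic `ceiling(n q)`, ties
#' resolved upward).
#'
#' @param rates trial x bin numeric matrix for one unit (spikes/s).
#' @param labels data frame with per-trial `grip` and `force`.
#' @param config a [cluster_test_config()].
#' @param timeline a [composite_timeline()] (provides segment boundaries).
#' @return Object of class `cluster_test`: per effect, a data frame of
#'   clusters (start/end bin, summed F, significant) plus the null
#'   threshold; also per-bin F and significance matrices and, for the force
#'   effect, the preferred force level of significant bins (see
#'   [preferred_force()]).
#' @export
test_unit <- function(rates, labels, config = cluster_test_config(),
                      timeline = composite_timeline()) {
  stopifnot(nrow(rates) == nrow(labels))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  n <- nrow(rates); nb <- ncol(rates)
  grip <- factor(labels$grip, levels = GRIPS)
  force <- factor(labels$force, levels = FORCES)
  cell <- as.integer(grip) + 2L * (as.integer(force) - 1L)   # 1..6
  counts <- tabulate(cell, 6)
  if (any(counts < 2)) stop("need >= 2 trials in every condition cell")
  des <- cell_designs()
  nperm <- config$n_permutations
  ## permuted cell sums: sparse indicator (6 cells x (nperm+1) blocks) x rates
  perms <- cbind(seq_len(n), replicate(nperm, sample.int(n)))
  i_idx <- rep(0:nperm, each = n) * 6L + cell[as.vector(perms)]
  P <- Matrix::sparseMatrix(i = i_idx, j = rep(seq_len(n), nperm + 1L),
                            x = 1, dims = c(6L * (nperm + 1L), n))
  S <- as.matrix(P %*% rates)                    # (6 (nperm+1)) x nb
  dim(S) <- c(6L, (nperm + 1L) * nb)
  tss <- colSums(rates^2)                        # permutation-invariant

  ## one stacked multiply for the four candidate designs
  p_sizes <- vapply(des$B, ncol, 0L)
  tBall <- do.call(rbind, lapply(des$B, t))      # sum(p) x 6
  Kall <- tBall %*% S                            # sum(p) x ((nperm+1) nb)
  row_off <- c(0L, cumsum(p_sizes))
  fit_ss <- lapply(seq_along(des$B), function(di) {
    B <- des$B[[di]]
    K <- Kall[row_off[di] + seq_len(p_sizes[di]), , drop = FALSE]
    G <- solve(crossprod(B, counts * B))
    m <- colSums(K * (G %*% K))
    matrix(m, nperm + 1L, nb)       # columns of S are perm-fastest per bin
  })
  names(fit_ss) <- names(des$B)
  df <- c(grip = 1, force = 2, interaction = 2)
  dfe <- n - 6L
  ss_err <- matrix(tss, nperm + 1L, nb, byrow = TRUE) - fit_ss$full
  ms_err <- ss_err / dfe
  Fm <- list(
    grip = (fit_ss$gf - fit_ss$f) / df["grip"] / ms_err,
    force = (fit_ss$gf - fit_ss$g) / df["force"] / ms_err,
    interaction = (fit_ss$full - fit_ss$gf) / df["interaction"] / ms_err)
  seg_ends <- as.integer(attr(timeline, "segment_ends"))

  out <- list()
  for (e in EFFECTS) {
    fcrit <- qf(1 - config$cluster_forming_p, df[[e]], dfe)
    Fe <- pmax(Fm[[e]], 0)
    null_max <- max_cluster_sums(Fe[-1, , drop = FALSE], fcrit, seg_ends)
    k <- min(nperm, ceiling(nperm * config$percentile / 100))
    thresh <- sort(null_max, partial = k)[k]
    cl <- find_clusters(Fe[1, ], fcrit, seg_ends)
    cl$significant <- cl$sum_F > thresh
    out[[e]] <- list(clusters = cl, null_threshold = thresh,
                     F = Fe[1, ], f_crit = fcrit)
  }
  res <- structure(list(effects = out, n_trials = n, config = config,
                        timeline = timeline),
                   class = "cluster_test")
  ## preferred force level over significant force bins
  sig_bins <- significant_bins(res, "force")
  if (any(sig_bins)) {
    fmeans <- vapply(FORCES, function(fl)
      colMeans(rates[force == fl, , drop = FALSE]), numeric(nb))
    res$preferred_force <- preferred_force(t(fmeans), sig_bins)
  }
  res
}

#' Per-bin significance mask of a cluster test
#'
#' @param x a `cluster_test`.
#' @param effect one of "grip", "force", "interaction".
#' @return Logical vector over bins, TRUE inside significant clusters.
#' @export
significant_bins <- function(x, effect) {
  nb <- length(x$effects[[effect]]$F)
  out <- logical(nb)
  cl <- x$effects[[effect]]$clusters
  for (i in seq_len(nrow(cl)))
    if (cl$significant[i]) out[cl$start[i]:cl$end[i]] <- TRUE
  out
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d trials, %d permutations, alpha = %g\n",
              x$n_trials, x$config$n_permutations, x$config$alpha))
  for (e in EFFECTS) {
    cl <- x$effects[[e]]$clusters
    cat(sprintf("  %-11s: %d cluster(s), %d significant (null thr %.1f)\n",
                e, nrow(cl), sum(cl$significant), x$effects[[e]]$null_threshold))
  }
  invisible(x)
}

#' Preferred force level in significant bins
#'
#' For each significant force-tuning bin, the force level with the maximal
#' grip-averaged firing rate. Exact ties are broken toward the lower force
#' level and logged in attribute `ties`.
#'
#' @param fmeans 3 x bins matrix of force-condition mean rates (rows in
#'   low/medium/high order, averaged over grips).
#' @param sig_bins logical vector of significant bins.
#' @return Character vector over bins: "low"/"medium"/"high" inside
#'   significant bins, NA elsewhere.
#' @export
preferred_force <- function(fmeans, sig_bins) {
  stopifnot(nrow(fmeans) == 3)
  out <- rep(NA_character_, ncol(fmeans))
  ties <- integer(0)
  for (b in which(sig_bins)) {
    mx <- max(fmeans[, b])
    winners <- which(fmeans[, b] == mx)
    if (length(winners) > 1) ties <- c(ties, b)
    out[b] <- FORCES[winners[1]]            # ties toward lower force
  }
  attr(out, "ties") <- ties
  out
}

#' Fraction of units tuned per time bin
#'
#' The per-bin fraction of units whose significant clusters (for a given
#' effect) cover that bin -- the population tuning time course.
#'
#' @param results list of `cluster_test` objects on a common timeline.
#' @return Matrix (3 effects x bins) of fractions in `[0, 1]`.
#' @export
population_fractions <- function(results) {
  nb <- vapply(results, function(r) length(r$effects$grip$F), 0L)
  if (length(unique(nb)) != 1) stop("units tested on different timelines")
  out <- matrix(0, 3, nb[1], dimnames = list(EFFECTS, NULL))
  for (e in EFFECTS) {
    cov <- vapply(results, significant_bins, logical(nb[1]), effect = e)
    out[e, ] <- rowMeans(cov)
  }
  out
}
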