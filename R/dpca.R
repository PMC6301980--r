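MARGS <- c("condition_independent", "force", "grip", "interaction")

## Broadcast an array defined over dims `dims` (subset of 1:4, always
## including the unit dim) back to the full (unit, force, grip, time) shape.
expand4 <- function(a, dims, d) {
  rest <- setdiff(1:4, dims)
  out <- array(a, c(d[dims], d[rest]))
  aperm(out, order(c(dims, rest)))
}

## Mean over the dims of a 4-D array not listed in `keep` (C-level fast).
mean_over <- function(x, keep) {
  d <- dim(x)
  rest <- setdiff(1:4, keep)
  y <- aperm(x, c(keep, rest))
  dim(y) <- c(prod(d[keep]), prod(d[rest]))
  out <- rowMeans(y)
  if (length(keep) > 1) dim(out) <- d[keep]
  out
}

#' Marginalization of a condition-labelled tensor
#'
#' Decomposes a trial-averaged tensor x(unit, force, grip, time) into eight
#' averaged terms: the grand mean, the pure time, force and grip terms, the
#' three pairwise interactions with time and between factors, and the
#' triple interaction. Each term is centered over every index it was
#' averaged over, so the terms sum back to the input exactly and are
#' mutually orthogonal on the balanced condition grid. The combined
#' marginalizations group the terms by task factor: condition-independent
#' (pure time), force (force + force-time), grip (grip + grip-time), and
#' interaction (force-grip + force-grip-time) -- each task factor keeps its
#' time interaction because all signals are expected to evolve over the
#' trial.
#'
#' @param x 4-D array (unit x force x grip x time). A single muscle's EMG
#'   can be passed with a unit dimension of length 1.
#' @return Object of class `marginalization_set`: `terms` (eight full-shape
#'   arrays: grand, t, f, g, tf, tg, fg, tfg), `combined` (four full-shape
#'   arrays), and `shares` (variance fractions of the combined
#'   marginalizations; they sum to 1 on a balanced grid).
#' @export
marginalize <- function(x) {
  stopifnot(length(dim(x)) == 4)
  if (!all(is.finite(x))) stop("tensor must be finite")
  d <- dim(x)
  grand <- mean_over(x, 1)
  xc <- x - expand4(grand, 1, d)
  bt <- mean_over(xc, c(1, 4))
  bf <- mean_over(xc, c(1, 2))
  bg <- mean_over(xc, c(1, 3))
  r <- xc - expand4(bt, c(1, 4), d) - expand4(bf, c(1, 2), d) -
    expand4(bg, c(1, 3), d)
  btf <- mean_over(r, c(1, 2, 4))
  btg <- mean_over(r, c(1, 3, 4))
  bfg <- mean_over(r, c(1, 2, 3))
  terms <- list(grand = expand4(grand, 1, d),
                t = expand4(bt, c(1, 4), d),
                f = expand4(bf, c(1, 2), d),
                g = expand4(bg, c(1, 3), d),
                tf = expand4(btf, c(1, 2, 4), d),
                tg = expand4(btg, c(1, 3, 4), d),
                fg = expand4(bfg, c(1, 2, 3), d))
  terms$tfg <- r - terms$tf - terms$tg - terms$fg
  combined <- list(condition_independent = terms$t,
                   force = terms$f + terms$tf,
                   grip = terms$g + terms$tg,
                   interaction = terms$fg + terms$tfg)
  tot <- sum(xc^2)
  shares <- vapply(combined, function(m) sum(m^2), 0) /
    if (tot > 0) tot else 1
  structure(list(terms = terms, combined = combined, shares = shares),
            class = "marginalization_set")
}

#' @export
print.marginalization_set <- function(x, ...) {
  cat("<marginalization_set> variance shares:\n")
  print(round(x$shares, 4))
  invisible(x)
}

flatten4 <- function(x) { d <- dim(x); dim(x) <- c(d[1], prod(d[-1])); x }

## (Pseudo-)inverse of XX' + lambda I; rank-deficient directions are dropped
## rather than inverted so lambda = 0 works on low-rank (noiseless) data.
ridge_inv <- function(XXt, lam_abs) {
  e <- eigen(XXt, symmetric = TRUE)
  v <- e$values + lam_abs
  tol <- max(v, 0) * 1e-12
  iv <- ifelse(v > tol, 1 / v, 0)
  e$vectors %*% (iv * t(e$vectors))
}

## ---------------------------------------------------------------------------

#' Demixed principal component analysis
#'
#' Fits demixed principal components to a firing-rate tensor: for each
#' combined marginalization X_phi of the trial-averaged data, solves the
#' reduced-rank ridge problem
#' min || X_phi - D_phi F_phi X ||^2 + lambda || D_phi F_phi ||^2
#' over rank-limited encoder D_phi and decoder F_phi, where X is the full
#' unit-centered trial-averaged matrix. The closed-form per-lambda solution
#' is the ridge regression of X_phi on X followed by a rank truncation via
#' the SVD of its fit. Components are ordered by the fraction of total
#' variance they explain; at most `n_components` are kept across all
#' marginalizations.
#'
#' When `x` is the 5-D trial-resolved tensor and `lambda = NULL`, the
#' regularization is selected on a grid (log-spaced, including 0, scaled to
#' the total variance) by `lambda_repetitions` rounds of held-out-trial
#' reconstruction error: in each round one random trial per unit and
#' condition forms a test matrix and the remaining trials are averaged for
#' training.
#'
#' For trial-resolved input the reported marginalization variance shares
#' are split-half signal-variance estimates: trials are split into random
#' halves and matching marginalizations of the two half-averages are
#' cross-multiplied, which cancels the trial-noise floor that inflates the
#' plug-in shares of a noisy trial average (the plug-in estimate is kept in
#' `marg_shares_plugin`).
#'
#' @param x 4-D trial-averaged array (unit x force x grip x time) or 5-D
#'   trial-resolved array (unit x force x grip x time x trial; NA for
#'   missing trials).
#' @param n_components maximum number of components overall (30 by
#'   default).
#' @param lambda fixed regularization strength, or NULL to cross-validate
#'   (5-D input) / use 0 (4-D input).
#' @param lambda_grid grid of relative regularization strengths; multiplied
#'   by the total variance of the training matrix. Must include 0.
#' @param lambda_repetitions held-out rounds for lambda selection.
#' @param seed integer seed for the held-out draws.
#' @return Object of class `dpca` with elements `encoder` (unit x K),
#'   `decoder` (K x unit), `marg` (marginalization label per component),
#'   `ev` (variance fraction per component), `cumulative_ev`,
#'   `marg_shares`, `pca_ev` (PCA spectrum of the same matrix), `scores`
#'   (component x force x grip x time array of component time courses),
#'   `lambda`, `lambda_cv`, `center`, `dims`.
#' @export
dpca <- function(x, n_components = 30, lambda = NULL,
                 lambda_grid = c(0, 10^seq(-7, -2.5, length.out = 10)),
                 lambda_repetitions = 10, seed = NULL) {
  nd <- length(dim(x))
  stopifnot(nd %in% c(4, 5))
  if (!0 %in% lambda_grid) stop("lambda grid must include 0")
  if (!is.null(seed)) set.seed(seed)
  xm <- if (nd == 5) rowMeans(x, dims = 4, na.rm = TRUE) else x
  d <- dim(xm)
  lambda_cv <- NULL
  if (is.null(lambda)) {
    if (nd == 5) {
      lambda_cv <- dpca_lambda_cv(x, lambda_grid, lambda_repetitions,
                                  n_components)
      lambda <- lambda_cv$lambda
    } else lambda <- 0
  }
  fit <- dpca_core(xm, n_components, lambda)
  if (nd == 5) {
    fit$marg_shares_plugin <- fit$marg_shares
    sh <- split_half_shares(x)
    if (!is.null(sh)) fit$marg_shares <- sh
  }
  fit$lambda_cv <- lambda_cv
  fit$call <- match.call()
  fit
}

dpca_core <- function(xm, n_components, lambda) {
  d <- dim(xm)
  N <- d[1]
  center <- mean_over(xm, 1)
  X <- flatten4(xm - expand4(center, 1, d))
  ss_tot <- sum(X^2)
  mg <- marginalize(xm)
  XXt <- tcrossprod(X)
  lam_abs <- lambda * ss_tot
  Cinv <- ridge_inv(XXt, lam_abs)
  enc <- dec <- list(); ev <- list(); labs <- list()
  dropped <- character(0)
  for (m in MARGS) {
    Xphi <- flatten4(mg$combined[[m]])
    if (sum(Xphi^2) / max(ss_tot, 1) < 1e-14) { dropped <- c(dropped, m); next }
    q <- min(n_components, N, ncol(X))
    A <- Xphi %*% crossprod(X, Cinv)            # N x N ridge coefficients
    ## left singular vectors of A X via the N x N Gram matrix A XX' A'
    H <- A %*% XXt %*% t(A)
    eh <- eigen((H + t(H)) / 2, symmetric = TRUE)
    q <- min(q, sum(eh$values > max(eh$values[1], 0) * 1e-12))
    U <- eh$vectors[, seq_len(q), drop = FALSE]
    Fm <- crossprod(U, A)                       # q x N decoders
    FX <- Fm %*% X
    UX <- crossprod(U, X)
    evm <- (2 * rowSums(FX * UX) - rowSums(FX^2)) / ss_tot
    enc[[m]] <- U; dec[[m]] <- Fm; ev[[m]] <- evm
    labs[[m]] <- rep(m, q)
  }
  ev_all <- unlist(ev); lab_all <- unlist(labs)
  ord <- order(ev_all, decreasing = TRUE)[seq_len(min(n_components, length(ev_all)))]
  encoder <- do.call(cbind, enc)[, ord, drop = FALSE]
  decoder <- do.call(rbind, dec)[ord, , drop = FALSE]
  K <- length(ord)
  ## cumulative explained variance of the top-k reconstructions
  R <- X; cum <- numeric(K)
  for (k in seq_len(K)) {
    R <- R - encoder[, k] %o% drop(decoder[k, , drop = FALSE] %*% X)
    cum[k] <- 1 - sum(R^2) / ss_tot
  }
  scores <- decoder %*% X
  dim(scores) <- c(K, d[2], d[3], d[4])
  dimnames(scores) <- list(NULL, FORCES, GRIPS, NULL)
  structure(list(encoder = encoder, decoder = decoder,
                 marg = lab_all[ord], ev = ev_all[ord], cumulative_ev = cum,
                 marg_shares = mg$shares,
                 pca_ev = { e <- eigen(XXt, symmetric = TRUE,
                                       only.values = TRUE)$values
                            pmax(e, 0) / ss_tot },
                 scores = scores, lambda = lambda, center = center,
                 dims = d, dropped = dropped, ss_tot = ss_tot),
            class = "dpca")
}

dpca_lambda_cv <- function(x5, grid, reps, n_components) {
  d <- dim(x5)
  N <- d[1]
  err <- matrix(0, reps, length(grid))
  for (r in seq_len(reps)) {
    test <- array(NA_real_, d[1:4])
    train <- array(NA_real_, d[1:4])
    for (f in 1:3) for (g in 1:2) {
      for (u in seq_len(N)) {
        avail <- which(!is.na(x5[u, f, g, 1, ]))
        j <- avail[sample.int(length(avail), 1)]
        test[u, f, g, ] <- x5[u, f, g, , j]
        train[u, f, g, ] <- rowMeans(x5[u, f, g, , avail[avail != j],
                                        drop = FALSE], na.rm = TRUE)
      }
    }
    ctr <- mean_over(train, 1)
    Xtr <- flatten4(train - expand4(ctr, 1, dim(train)))
    Xte <- flatten4(test - expand4(ctr, 1, dim(test)))
    mg_tr <- marginalize(train)
    mg_te <- marginalize(test)
    XXt <- tcrossprod(Xtr)
    ss <- sum(Xtr^2)
    ed <- eigen(XXt, symmetric = TRUE)
    ## per-marginalization sufficient statistics: everything per lambda then
    ## runs in the N x N unit space
    stats_m <- lapply(MARGS, function(m) {
      Xphi <- flatten4(mg_tr$combined[[m]])
      if (sum(Xphi^2) / max(ss, 1) < 1e-14) return(NULL)
      Mte <- flatten4(mg_te$combined[[m]])
      list(G = Xphi %*% t(Xtr), MX = Mte %*% t(Xte), ss_te = sum(Mte^2))
    })
    XteXte <- Xte %*% t(Xte)
    for (li in seq_along(grid)) {
      v <- ed$values + grid[li] * ss
      tol <- max(v, 0) * 1e-12
      Cinv <- ed$vectors %*% (ifelse(v > tol, 1 / v, 0) * t(ed$vectors))
      for (sm in stats_m) {
        if (is.null(sm)) next
        A <- sm$G %*% Cinv
        H <- A %*% XXt %*% t(A)
        eh <- eigen((H + t(H)) / 2, symmetric = TRUE)
        q <- min(n_components, sum(eh$values > max(eh$values[1], 0) * 1e-12))
        U <- eh$vectors[, seq_len(q), drop = FALSE]
        B <- U %*% crossprod(U, A)              # rank-limited map
        err[r, li] <- err[r, li] + sm$ss_te -
          2 * sum(B * sm$MX) + sum(diag(crossprod(B) %*% XteXte))
      }
    }
  }
  me <- colMeans(err)
  list(lambda = grid[which.min(me)], grid = grid, error = me)
}

## Unbiased marginalization signal-variance shares from trial-resolved data:
## trials are split into random halves, each half averaged and marginalized,
## and the cross inner product of matching marginalizations taken -- noise
## is independent between halves, so its contribution cancels in
## expectation (the plug-in share of a noisy average is inflated by the
## trial-noise floor instead).
split_half_shares <- function(x5, n_splits = 5) {
  d <- dim(x5); n <- d[5]
  if (n < 2) return(NULL)
  ss <- matrix(0, n_splits, length(MARGS), dimnames = list(NULL, MARGS))
  for (s in seq_len(n_splits)) {
    ia <- sample.int(n, floor(n / 2))
    avgA <- rowMeans(x5[, , , , ia, drop = FALSE], dims = 4, na.rm = TRUE)
    avgB <- rowMeans(x5[, , , , -ia, drop = FALSE], dims = 4, na.rm = TRUE)
    mgA <- marginalize(avgA); mgB <- marginalize(avgB)
    ss[s, ] <- vapply(MARGS, function(m)
      sum(mgA$combined[[m]] * mgB$combined[[m]]), 0)
  }
  ssm <- pmax(colMeans(ss), 0)
  ssm / sum(ssm)
}

#' @export
print.dpca <- function(x, ...) {
  cat(sprintf("Demixed PCA: %d components over %d units, lambda = %g\n",
              length(x$ev), x$dims[1], x$lambda))
  cat("marginalization variance shares:\n")
  print(round(x$marg_shares, 4))
  cat(sprintf("top component: %s (%.1f%% of variance); first %d components: %.1f%%\n",
              x$marg[1], 100 * x$ev[1], length(x$ev),
              100 * x$cumulative_ev[length(x$ev)]))
  invisible(x)
}

#' @export
summary.dpca <- function(object, ...) {
  tab <- data.frame(component = seq_along(object$ev), marg = object$marg,
                    ev = object$ev, cumulative_ev = object$cumulative_ev)
  by_marg <- vapply(MARGS, function(m)
    sum(object$ev[object$marg == m]), 0)
  out <- list(components = tab, marg_shares = object$marg_shares,
              component_ev_by_marg = by_marg,
              pca_cumulative = cumsum(object$pca_ev),
              lambda = object$lambda)
  class(out) <- "summary.dpca"
  out
}

#' @export
print.summary.dpca <- function(x, ...) {
  cat("Demixed PCA summary\n\nvariance shares of the marginalizations:\n")
  print(round(x$marg_shares, 4))
  cat("\nleading components:\n")
  tab <- x$components
  tab$ev <- round(tab$ev, 4)
  tab$cumulative_ev <- round(tab$cumulative_ev, 4)
  print(head(tab, 10))
  invisible(x)
}

#' @export
coef.dpca <- function(object, type = c("decoder", "encoder"), ...) {
  type <- match.arg(type)
  if (type == "decoder") object$decoder else object$encoder
}

#' Project data onto demixed components
#'
#' @param object a fitted [dpca()] model.
#' @param newdata 4-D tensor (unit x force x grip x time) or unit x D
#'   matrix; defaults to the training scores.
#' @param ... unused.
#' @return component x D matrix of projections (unit means from the fit are
#'   removed first).
#' @export
predict.dpca <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  Xn <- if (length(dim(newdata)) == 4)
    flatten4(newdata - expand4(object$center, 1, dim(newdata)))
  else newdata - object$center
  object$decoder %*% Xn
}

#' Plot demixed component time courses
#'
#' One panel per marginalization, showing the largest component's time
#' course for every condition (solid: whole-hand, dashed: precision; line
#' shade: force level) on the composite timeline.
#'
#' @param x a fitted [dpca()] model.
#' @param components which component of each marginalization to show.
#' @param timeline optional [composite_timeline()] for segment boundaries.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.dpca <- function(x, components = 1, timeline = NULL, ...) {
  margs <- intersect(MARGS, unique(x$marg))
  op <- graphics::par(mfrow = c(length(margs), 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- c(low = "red3", medium = "green4", high = "blue3")
  for (m in margs) {
    idx <- which(x$marg == m)[components]
    idx <- idx[!is.na(idx)]
    for (k in idx) {
      y <- matrix(aperm(x$scores[k, , , , drop = FALSE], c(4, 2, 3, 1)),
                  ncol = 6)
      graphics::matplot(y, type = "l", lty = rep(c(1, 2), each = 3),
                        col = rep(cols, 2), xlab = "bin", ylab = "a.u.",
                        main = sprintf("%s dPC %d (%.1f%%)", m,
                                       which(idx == k), 100 * x$ev[k]), ...)
      if (!is.null(timeline))
        graphics::abline(v = attr(timeline, "segment_ends"), col = "grey")
    }
  }
  invisible(x)
}
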