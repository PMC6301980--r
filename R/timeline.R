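#' Alignment specification for the composite PSTH timeline
#'
#' Firing rates are assembled from three event-aligned windows: cue onset
#' (-400 to +1300 ms), handle touch (-500 to +500 ms), and reward onset
#' (-1000 to +200 ms). Rates are estimated at 1 ms resolution after Gaussian
#' smoothing (sigma = 50 ms) and analysed in 10 ms bins, giving
#' (1700 + 1000 + 1200) / 10 = 390 analysis bins.
#'
#' @param cue,touch,reward two-element numeric windows in ms relative to the
#'   alignment event.
#' @param sigma_ms rate smoothing kernel standard deviation (ms).
#' @param bin_ms analysis bin width (ms).
#' @return An object of class `alignment_spec`.
#' @export
alignment_spec <- function(cue = c(-400, 1300), touch = c(-500, 500),
                           reward = c(-1000, 200), sigma_ms = 50, bin_ms = 10) {
  windows <- list(cue = cue, touch = touch, reward = reward)
  for (w in windows) {
    stopifnot(length(w) == 2, w[2] > w[1])
    if (any((w %% bin_ms) != 0)) stop("window edges must be multiples of bin_ms")
  }
  structure(list(windows = windows, sigma_ms = sigma_ms, bin_ms = bin_ms),
            class = "alignment_spec")
}

#' Composite analysis timeline
#'
#' Bin centers for the concatenated alignment segments. Bins are `bin_ms`
#' wide; the center of the first bin of a window `(a, b)` sits at
#' `a + bin_ms/2`.
#'
#' @param spec an [alignment_spec()].
#' @return An object of class `composite_timeline`: data frame with columns
#'   `segment` (factor cue/touch/reward) and `center` (ms relative to that
#'   segment's alignment event), plus attributes `bin_ms` and
#'   `segment_ends` (last bin index of each segment).
#' @export
composite_timeline <- function(spec = alignment_spec()) {
  segs <- lapply(names(spec$windows), function(nm) {
    w <- spec$windows[[nm]]
    centers <- seq(w[1] + spec$bin_ms / 2, w[2] - spec$bin_ms / 2, by = spec$bin_ms)
    data.frame(segment = nm, center = centers, stringsAsFactors = FALSE)
  })
  tl <- do.call(rbind, segs)
  tl$segment <- factor(tl$segment, levels = names(spec$windows))
  attr(tl, "bin_ms") <- spec$bin_ms
  attr(tl, "segment_ends") <- cumsum(table(tl$segment)[levels(tl$segment)])
  class(tl) <- c("composite_timeline", "data.frame")
  tl
}

#' @export
print.composite_timeline <- function(x, ...) {
  ends <- attr(x, "segment_ends")
  cat("Composite timeline:", nrow(x), "bins of", attr(x, "bin_ms"), "ms\n")
  start <- 1L
  for (i in seq_along(ends)) {
    cat(sprintf("  %-7s bins %3d-%3d  (%g to %g ms)\n", names(ends)[i],
                start, ends[i], x$center[start], x$center[ends[i]]))
    start <- ends[i] + 1L
  }
  invisible(x)
}

n_bins <- function(spec = alignment_spec()) {
  sum(vapply(spec$windows, function(w) diff(w) / spec$bin_ms, 0))
}

## Indices (on the 10-ms composite timeline) of reward-segment bins whose
## real time duplicates the tail of the touch segment when median AT < 500 ms:
## reward-aligned bins with center < -(median_AT + 500).
overlap_bins <- function(timeline, median_at) {
  if (!is.finite(median_at) || median_at >= 500) return(integer(0))
  which(timeline$segment == "reward" & timeline$center < -(median_at + 500))
}
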