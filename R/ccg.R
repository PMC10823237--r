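#' Cross-correlogram of two spike trains
#'
#' Counts post-minus-pre spike-time differences in half-open lag bins
#' \[lo, hi) of width `binMs` over \[-maxLagMs, +maxLagMs\].  Both trains
#' must be sorted ascending.  An empty presynaptic train yields an
#' all-zero CCG with a warning.
#'
#' @param preTimes,postTimes sorted spike times, seconds.
#' @param binMs bin width in ms (default 0.1).
#' @param maxLagMs maximum |lag| in ms (default 10).
#' @return list: `lagsMs` (bin centers), `counts`.
#' @export
computeCcg <- function(preTimes, postTimes, binMs = 0.1, maxLagMs = 10) {
  if (binMs <= 0) stop("invalid-argument: binMs must be > 0")
  edges <- seq(-maxLagMs, maxLagMs, by = binMs)
  lags <- edges[-length(edges)] + binMs / 2
  if (!length(preTimes)) {
    warning("empty presynaptic train: all-zero CCG")
    return(list(lagsMs = lags, counts = numeric(length(lags))))
  }
  counts <- .binnedLagCounts(preTimes, postTimes, edges)
  list(lagsMs = lags, counts = counts)
}

# Core binning: for each pre spike, take all post spikes within the lag
# range and histogram the differences (ms) into half-open bins.
.binnedLagCounts <- function(pre, post, edgesMs) {
  nb <- length(edgesMs) - 1L
  if (!length(post)) return(numeric(nb))
  loS <- edgesMs[1] / 1000
  hiS <- edgesMs[length(edgesMs)] / 1000
  i0 <- findInterval(pre + loS, post, left.open = TRUE)   # post <= pre+lo excluded
  i1 <- findInterval(pre + hiS, post)                     # post <= pre+hi included
  nPer <- i1 - i0
  keep <- nPer > 0L
  if (!any(keep)) return(numeric(nb))
  postIdx <- sequence(nPer[keep]) + rep(i0[keep], nPer[keep])
  diffsMs <- (post[postIdx] - rep(pre[keep], nPer[keep])) * 1000
  bin <- findInterval(diffsMs, edgesMs)                    # [edge_i, edge_{i+1})
  bin <- bin[bin >= 1L & bin <= nb]
  tabulate(bin, nbins = nb)
}

#' Jitter-corrected cross-correlogram
#'
#' Estimates the slow (co-modulation) component of a CCG by re-drawing
#' every postsynaptic spike uniformly within its own fixed wall-clock
#' window of `jitterWindowMs` (default 10 ms; window k is
#' \[k w, (k+1) w)), recomputing the CCG over `nSurrogates` such
#' surrogates, and subtracting the surrogate mean from the raw CCG.
#' Millisecond-scale structure (monosynaptic peaks) survives; rate
#' covariations slower than the window cancel.  Only the postsynaptic
#' train is jittered (equivalent in expectation, half the cost).
#' Deterministic for a fixed seed.
#'
#' @param preTimes,postTimes sorted spike times, seconds.
#' @param binMs CCG bin width, ms.
#' @param maxLagMs maximum |lag|, ms.
#' @param jitterWindowMs jitter window, ms; must exceed `binMs`.
#' @param nSurrogates surrogate count (default 50).
#' @param seed integer seed.
#' @return a [CorrectedCCG-class]
#' @export
jitterCorrect <- function(preTimes, postTimes, binMs = 0.1, maxLagMs = 10,
                          jitterWindowMs = 10, nSurrogates = 50, seed) {
  if (missing(seed)) stop("invalid-argument: seed is required")
  if (jitterWindowMs <= binMs)
    stop("invalid-argument: jitter window must exceed the bin width")
  edges <- seq(-maxLagMs, maxLagMs, by = binMs)
  lags <- edges[-length(edges)] + binMs / 2
  nb <- length(lags)
  raw <- if (length(preTimes)) .binnedLagCounts(preTimes, postTimes, edges)
         else numeric(nb)

  jm <- numeric(nb)
  if (length(preTimes) && length(postTimes)) {
    set.seed(as.integer(seed))
    wS <- jitterWindowMs / 1000
    winBase <- floor(postTimes / wS) * wS
    for (s in seq_len(nSurrogates)) {
      surr <- sort(winBase + stats::runif(length(postTimes)) * wS)
      jm <- jm + .binnedLagCounts(preTimes, surr, edges)
    }
    jm <- jm / nSurrogates
  }
  new("CorrectedCCG", lagsMs = lags, rawCounts = as.numeric(raw),
      jitterMean = jm, binMs = binMs, jitterWindowMs = jitterWindowMs,
      nPre = length(preTimes), nPost = length(postTimes))
}

#' Construct a CorrectedCCG from components
#'
#' Low-level constructor, mainly for building synthetic correlograms in
#' tests and examples.
#'
#' @param lagsMs bin centers (ms).
#' @param rawCounts,jitterMean per-bin counts and surrogate mean.
#' @param binMs bin width (ms).
#' @param jitterWindowMs jitter window width (ms).
#' @param nPre,nPost spike counts.
#' @return a [CorrectedCCG-class]
#' @export
correctedCcg <- function(lagsMs, rawCounts, jitterMean = numeric(length(lagsMs)),
                         binMs = diff(lagsMs[1:2]), jitterWindowMs = 10,
                         nPre = 0L, nPost = 0L) {
  new("CorrectedCCG", lagsMs = lagsMs, rawCounts = as.numeric(rawCounts),
      jitterMean = as.numeric(jitterMean), binMs = binMs,
      jitterWindowMs = jitterWindowMs,
      nPre = as.integer(nPre), nPost = as.integer(nPost))
}

#' @rdname correctedCounts
setMethod("correctedCounts", "CorrectedCCG", function(x) x@rawCounts - x@jitterMean)

#' @rdname rawCounts
setMethod("rawCounts", "CorrectedCCG", function(x) x@rawCounts)

#' @rdname lagsMs
setMethod("lagsMs", "CorrectedCCG", function(x) x@lagsMs)

#' @rdname baselineSd
setMethod("baselineSd", "CorrectedCCG", function(x) {
  sel <- x@lagsMs >= -4.5 & x@lagsMs <= 0.5
  stats::sd(correctedCounts(x)[sel])
})

setMethod("show", "CorrectedCCG", function(object) {
  cat(sprintf(
    "CorrectedCCG: %d bins of %g ms over [%g, %g] ms, nPre=%d nPost=%d, baseline SD %.3g\n",
    length(object@lagsMs), object@binMs, min(object@lagsMs) - object@binMs / 2,
    max(object@lagsMs) + object@binMs / 2, object@nPre, object@nPost,
    baselineSd(object)))
})
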