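#' Detect a monosynaptic connection in a corrected CCG
#'
#' A connection is declared when at least `minBins` consecutive bins
#' whose centers lie within the monosynaptic window (0.5 to 4 ms) exceed
#' `sdThresh` (default 3) times the baseline SD of the corrected CCG
#' (measured over -4.5 to 0.5 ms).  The peak lag is the lag of the
#' largest corrected bin among the significant bins.
#'
#' @param ccg a [CorrectedCCG-class].
#' @param sdThresh significance threshold in baseline SDs.
#' @param minBins minimum run length of significant bins.
#' @param windowMs monosynaptic lag window (ms).
#' @return list of class `"connection"` (`peakLagMs`, `peakHeightSd`,
#'   `sigBins` = indices into the lag axis of the qualifying run), or
#'   `NULL` when no connection is detected.
#' @export
detectConnection <- function(ccg, sdThresh = 3, minBins = 4L,
                             windowMs = c(0.5, 4)) {
  sdB <- baselineSd(ccg)
  if (!is.finite(sdB) || sdB == 0)
    stop("degenerate baseline: corrected CCG has zero baseline SD, detection refused")
  corr <- correctedCounts(ccg)
  lags <- lagsMs(ccg)
  inWin <- lags >= windowMs[1] & lags <= windowMs[2]
  sig <- inWin & corr > sdThresh * sdB
  if (!any(sig)) return(NULL)

  # runs of consecutive significant bins
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- which(r$values & r$lengths >= minBins)
  if (!length(qual)) return(NULL)

  # among qualifying runs, take the one holding the tallest bin
  bestRun <- qual[which.max(vapply(qual, function(q)
    max(corr[starts[q]:ends[q]]), 1))]
  bins <- starts[bestRun]:ends[bestRun]
  pk <- bins[which.max(corr[bins])]
  structure(list(
    peakLagMs = lags[pk],
    peakHeightSd = corr[pk] / sdB,
    sigBins = bins
  ), class = "connection")
}

#' Spike transmission efficacy
#'
#' Area under the monosynaptic peak of the jitter-corrected CCG divided
#' by the presynaptic spike count: the probability that a presynaptic
#' spike drives an extra postsynaptic spike.  The integration window is
#' the detected significant run extended outward over adjacent bins
#' still above 1 baseline SD; the result is clipped at 0.
#'
#' Because every evoked coincidence is itself redistributed across the
#' jitter window by the surrogates, the corrected area under-counts the
#' peak by the factor (1 - W/J), with W the integration window width and
#' J the jitter window; the area is rescaled by its inverse (W/J capped
#' at 0.5), which is exact in expectation because the surrogate interval
#' of every evoked spike covers the peak lag.
#'
#' @param ccg a [CorrectedCCG-class].
#' @param connection a [detectConnection()] result.
#' @param extendSd extension threshold in baseline SDs.
#' @return efficacy as a fraction (>= 0)
#' @export
connectionEfficacy <- function(ccg, connection, extendSd = 1) {
  if (is.null(connection)) stop("invalid-argument: no connection supplied")
  if (ccg@nPre == 0L) return(NA_real_)
  corr <- correctedCounts(ccg)
  sdB <- baselineSd(ccg)
  lo <- connection$sigBins[1]
  hi <- connection$sigBins[length(connection$sigBins)]
  while (lo > 1L && corr[lo - 1L] > extendSd * sdB) lo <- lo - 1L
  while (hi < length(corr) && corr[hi + 1L] > extendSd * sdB) hi <- hi + 1L
  widthMs <- (hi - lo + 1L) * ccg@binMs
  selfLoss <- min(widthMs / ccg@jitterWindowMs, 0.5)
  max(0, sum(corr[lo:hi]) / (1 - selfLoss) / ccg@nPre)
}
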