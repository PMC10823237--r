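#' Spike-triggered average of a postsynaptic probe
#'
#' Averages the spike-band signal of the postsynaptic probe at
#' presynaptic spike times, revealing the presynaptic axon's synaptic
#' footprint.  Presynaptic spikes within `exclusionMs` (default 1 ms) of
#' any postsynaptic spike are removed first, so postsynaptic somatic
#' spiking cannot contaminate the average; of the remainder at most
#' `nMax` (default 20000) seed-deterministically sampled triggers are
#' used.
#'
#' @param recPost the postsynaptic-probe [RawRecording-class].
#' @param preTimes presynaptic spike times, seconds (sorted).
#' @param postTimes postsynaptic spike times for the exclusion, or `NULL`.
#' @param nMax trigger cap.
#' @param exclusionMs exclusion half-window, ms.
#' @param windowMs lag window around the trigger (ms).
#' @param seed integer seed for the subsample.
#' @return a [StaMap-class]
#' @export
computeSta <- function(recPost, preTimes, postTimes = NULL, nMax = 20000,
                       exclusionMs = 1, windowMs = c(-5, 10), seed = 1) {
  trig <- preTimes
  if (!is.null(postTimes) && length(postTimes)) {
    # distance to the nearest postsynaptic spike
    idx <- findInterval(trig, postTimes)
    dLeft <- ifelse(idx >= 1L, trig - postTimes[pmax(idx, 1L)], Inf)
    dRight <- ifelse(idx < length(postTimes),
                     postTimes[pmin(idx + 1L, length(postTimes))] - trig, Inf)
    trig <- trig[pmin(dLeft, dRight) > exclusionMs / 1000]
  }
  excluded <- length(preTimes) - length(trig)
  fs <- samplingRate(recPost)
  nSamp <- ncol(recPost@samples)
  preSamp <- as.integer(round(-windowMs[1] / 1000 * fs))
  postSamp <- as.integer(round(windowMs[2] / 1000 * fs))
  centers <- as.integer(round(trig * fs)) + 1L
  keep <- centers - preSamp >= 1L & centers + postSamp <= nSamp
  trig <- trig[keep]
  centers <- centers[keep]
  if (!length(centers))
    stop("empty-input: no presynaptic trigger left after exclusion")
  if (length(centers) > nMax) {
    set.seed(as.integer(seed))
    sel <- sort(sample(seq_along(centers), nMax))
    centers <- centers[sel]
    trig <- trig[sel]
  }
  acc <- matrix(0, nrow(recPost@samples), preSamp + postSamp + 1L)
  for (c0 in centers)
    acc <- acc + recPost@samples[, (c0 - preSamp):(c0 + postSamp)]
  lags <- seq(windowMs[1], windowMs[2], by = 1000 / fs)
  new("StaMap", values = acc / length(centers), lagsMs = lags,
      samplingRate = fs, nSpikesUsed = length(centers),
      excludedSpikes = as.integer(excluded), triggerTimes = trig)
}

#' Axonal footprint of an STA map
#'
#' Reads the STA at the postsynaptic neuron's peak channel and at the
#' axonal response lag -- the CCG peak lag minus 1 ms, rounded to the
#' nearest sample -- and counts the channels whose STA value at that lag
#' crosses the threshold (default -0.75 uV).  Width 0 means no
#' measurable footprint ("n.d.").
#'
#' @param sta a [StaMap-class].
#' @param postPeakChannel peak channel of the postsynaptic neuron.
#' @param ccgPeakLagMs CCG peak lag of the connection, ms.
#' @param threshUv detection threshold in uV (negative).
#' @param responseOffsetMs lag offset from the CCG peak, ms.
#' @return list of class `"staFootprint"`: `amplitudeUv`,
#'   `widthChannels`, `detected`, `responseLagMs`.
#' @export
staFootprint <- function(sta, postPeakChannel, ccgPeakLagMs,
                         threshUv = -0.75, responseOffsetMs = 1) {
  lag <- ccgPeakLagMs - responseOffsetMs
  if (lag < min(sta@lagsMs) || lag > max(sta@lagsMs))
    stop("invalid-argument: response lag outside the STA window")
  col <- which.min(abs(sta@lagsMs - lag))
  amp <- sta@values[postPeakChannel, col]
  width <- sum(sta@values[, col] < threshUv)
  structure(list(
    amplitudeUv = amp, widthChannels = as.integer(width),
    detected = width > 0L, responseLagMs = sta@lagsMs[col]
  ), class = "staFootprint")
}

#' @rdname waveformValues
setMethod("waveformValues", "StaMap", function(x) x@values)

#' @rdname samplingRate
setMethod("samplingRate", "StaMap", function(x) x@samplingRate)

#' @rdname timesMs
setMethod("timesMs", "StaMap", function(x) x@lagsMs)

setMethod("show", "StaMap", function(object) {
  cat(sprintf("StaMap: %d channels x %d lags [%g, %g] ms, %d triggers (%d excluded)\n",
    nrow(object@values), ncol(object@values), min(object@lagsMs),
    max(object@lagsMs), object@nSpikesUsed, object@excludedSpikes))
})
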