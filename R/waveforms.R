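#' Correct per-ADC sample-time offsets
#'
#' Channels of one ADC are digitized sequentially, so a channel of rank r
#' is acquired r x 2.78 us after its group's first channel.  The
#' correction advances each channel by its rank's offset via band-limited
#' (FFT phase) interpolation, restoring a common time base; rank-0
#' channels are untouched and the operation is the identity when all
#' ranks are 0.
#'
#' @param x channels x time numeric matrix, or a
#'   [MultiChannelWaveform-class].
#' @param layout a [ProbeLayout-class] supplying `adcRank`.
#' @param samplingRate Hz (taken from `x` when it is a waveform object).
#' @param staggerUs per-rank offset in us.
#' @return object of the same type as `x`
#' @export
correctAdcOffsets <- function(x, layout, samplingRate = 30000, staggerUs = 2.78) {
  if (is(x, "MultiChannelWaveform")) {
    x@values <- .adcShift(x@values, layout, x@samplingRate,
                          direction = -1, staggerUs = staggerUs)
    return(x)
  }
  .adcShift(x, layout, samplingRate, direction = -1, staggerUs = staggerUs)
}

#' Extract the multichannel waveform (MCW) of a unit
#'
#' Averages peri-spike snippets of the spike-band signal over all spike
#' times (up to `maxSpikes`; beyond that a seed-deterministic random
#' subsample is used), then applies the per-ADC sample-time correction.
#' The peak channel is the channel with the largest |trough|, ties going
#' to the lowest index.
#'
#' @param rec a [RawRecording-class].
#' @param spikeTimesS spike times in seconds.
#' @param maxSpikes cap on snippets averaged (default 50000).
#' @param windowMs peri-spike window (ms); the default `c(-5, 5)` covers
#'   the propagation-analysis baseline.
#' @param seed integer seed for the subsample (only used when the cap
#'   binds).
#' @return a [MultiChannelWaveform-class]
#' @export
extractMcw <- function(rec, spikeTimesS, maxSpikes = 50000,
                       windowMs = c(-5, 5), seed = 1) {
  fs <- samplingRate(rec)
  nSamp <- ncol(rec@samples)
  preSamp <- as.integer(round(-windowMs[1] / 1000 * fs))
  postSamp <- as.integer(round(windowMs[2] / 1000 * fs))
  centers <- as.integer(round(spikeTimesS * fs)) + 1L
  centers <- centers[centers - preSamp >= 1L & centers + postSamp <= nSamp]
  if (!length(centers)) stop("empty-input: no spike with a full window inside the recording")
  if (length(centers) > maxSpikes) {
    set.seed(as.integer(seed))
    centers <- sort(sample(centers, maxSpikes))
  }
  lt <- preSamp + postSamp + 1L
  acc <- matrix(0, nrow(rec@samples), lt)
  for (c0 in centers)
    acc <- acc + rec@samples[, (c0 - preSamp):(c0 + postSamp)]
  values <- acc / length(centers)
  values <- .adcShift(values, rec@layout, fs, direction = -1)
  pk <- which.min(apply(values, 1L, min))  # first index wins ties
  new("MultiChannelWaveform", values = values, windowMs = as.numeric(windowMs),
      samplingRate = fs, nSpikesUsed = length(centers), peakChannel = as.integer(pk))
}

# peak-to-peak per channel, optionally over a column subset
.p2pProfile <- function(values, cols = seq_len(ncol(values))) {
  apply(values[, cols, drop = FALSE], 1L, function(v) max(v) - min(v))
}

# last index in [from, to] where v <= 0 (the AF/DF boundary), or NA
.zeroCrossing <- function(v, from, to) {
  idx <- from:to
  nonpos <- idx[v[idx] <= 0]
  if (!length(nonpos)) NA_integer_ else max(nonpos)
}

#' Waveform amplitude and spread metrics
#'
#' Positive/negative peak amplitudes at the peak channel, the spatial
#' spread (number of channels whose peak-to-peak profile exceeds 0.1 of
#' the maximum, and their vertical extent in um), and the rebound -- the
#' largest positive excursion after the trough -- with its duration at
#' half height and its own spatial spread measured over the post-rebound
#' (DF) time window.
#'
#' @param mcw a [MultiChannelWaveform-class].
#' @param layout the matching [ProbeLayout-class].
#' @param profileThresh spread threshold on the normalized profile.
#' @return list of class `"waveformMetrics"`: `posPeakUv`, `negPeakUv`,
#'   `spreadChannels`, `spreadUm`, `reboundDurationMs`,
#'   `reboundSpreadChannels`, `peakChannel`.
#' @export
waveformMetrics <- function(mcw, layout, profileThresh = 0.1) {
  values <- waveformValues(mcw)
  if (all(values == 0)) stop("degenerate-waveform: all-zero MCW")
  tMs <- timesMs(mcw)
  dt <- 1000 / mcw@samplingRate
  y <- channelPositions(layout)[, "y"]

  prof <- .p2pProfile(values)
  prof <- prof / max(prof)
  supra <- prof > profileThresh
  spreadChannels <- sum(supra)
  # a single supra-threshold row still occupies one pitch of tissue
  spreadUm <- diff(range(y[supra])) + layout@verticalPitch

  pc <- peakChannel(mcw)
  v <- values[pc, ]
  troughIdx <- which.min(v)
  negPeak <- v[troughIdx]
  posPeak <- max(v)

  reboundDur <- 0
  reboundSpread <- 0L
  nt <- length(v)
  if (troughIdx < nt && max(v[(troughIdx + 1L):nt]) > 0) {
    rbIdx <- troughIdx + which.max(v[(troughIdx + 1L):nt])
    half <- v[rbIdx] / 2
    lo <- rbIdx; while (lo > 1L && v[lo - 1L] >= half) lo <- lo - 1L
    hi <- rbIdx; while (hi < nt && v[hi + 1L] >= half) hi <- hi + 1L
    reboundDur <- (hi - lo + 1L) * dt
    zc <- .zeroCrossing(v, troughIdx, rbIdx)
    dfFrom <- if (is.na(zc)) troughIdx + 1L else zc + 1L
    dfProf <- .p2pProfile(values, dfFrom:nt)
    dfProf <- dfProf / max(dfProf)
    reboundSpread <- sum(dfProf > profileThresh)
  }

  structure(list(
    posPeakUv = posPeak, negPeakUv = negPeak,
    spreadChannels = as.integer(spreadChannels), spreadUm = spreadUm,
    reboundDurationMs = reboundDur,
    reboundSpreadChannels = as.integer(reboundSpread),
    peakChannel = pc
  ), class = "waveformMetrics")
}

#' Classify a unit as thalamocortical axon or cortical soma
#'
#' A unit is a TCA when its waveform carries a second large rebound peak
#' longer than 1 ms spread over more than 10 channels; otherwise it is a
#' V1N when a clear somatic trough is present, and unclassified when the
#' waveform is sub-threshold.
#'
#' @param metrics a [waveformMetrics()] result.
#' @param reboundMsThresh rebound duration criterion (ms), exclusive.
#' @param reboundSpreadThresh rebound spread criterion (channels), exclusive.
#' @param minTroughUv minimum |trough| (uV) for a clear somatic waveform.
#' @return `"TCA"`, `"V1N"` or `"unclassified"`
#' @export
classifyUnit <- function(metrics, reboundMsThresh = 1,
                         reboundSpreadThresh = 10, minTroughUv = 10) {
  if (metrics$reboundDurationMs > reboundMsThresh &&
      metrics$reboundSpreadChannels > reboundSpreadThresh) return("TCA")
  if (metrics$negPeakUv <= -minTroughUv) return("V1N")
  "unclassified"
}

# amplitude/spread metrics of one temporal segment of an MCW
.segmentMetrics <- function(values, layout, profileThresh = 0.1) {
  prof <- .p2pProfile(values)
  best <- which.max(prof)
  profN <- prof / max(prof)
  supra <- profN > profileThresh
  y <- channelPositions(layout)[, "y"]
  list(
    posPeakUv = max(values[best, ]), negPeakUv = min(values[best, ]),
    spreadChannels = as.integer(sum(supra)),
    spreadUm = diff(range(y[supra])) + layout@verticalPitch,
    peakChannel = as.integer(best)
  )
}

#' Split a TCA waveform into axonal and dendritic fields
#'
#' Temporal split at the zero crossing between the first trough and the
#' rebound peak at the peak channel: the earlier segment is the axonal
#' field (AF), the later the dendritic/synaptic contact field (DF).
#' Amplitude and spread metrics are computed for each segment.
#'
#' @param mcw a [MultiChannelWaveform-class].
#' @param layout the matching [ProbeLayout-class].
#' @param label unit label; anything but `"TCA"` is refused.
#' @return list: `af`, `df` ([MultiChannelWaveform-class] segments),
#'   `afMetrics`, `dfMetrics`, `splitMs`.
#' @export
splitAfDf <- function(mcw, layout, label = "TCA") {
  if (!identical(label, "TCA"))
    stop("decomposition refused: unit is not classified TCA")
  values <- waveformValues(mcw)
  tMs <- timesMs(mcw)
  v <- values[peakChannel(mcw), ]
  troughIdx <- which.min(v)
  nt <- length(v)
  if (troughIdx >= nt || max(v[(troughIdx + 1L):nt]) <= 0)
    stop("decomposition-failure: no rebound after the trough")
  rbIdx <- troughIdx + which.max(v[(troughIdx + 1L):nt])
  zc <- .zeroCrossing(v, troughIdx, rbIdx)
  if (is.na(zc)) stop("decomposition-failure: no zero crossing between trough and rebound")

  mkSeg <- function(cols) {
    new("MultiChannelWaveform", values = values[, cols, drop = FALSE],
        windowMs = c(tMs[cols[1]], tMs[cols[length(cols)]]),
        samplingRate = mcw@samplingRate, nSpikesUsed = mcw@nSpikesUsed,
        peakChannel = peakChannel(mcw))
  }
  afCols <- 1L:zc
  dfCols <- (zc + 1L):nt
  list(
    af = mkSeg(afCols), df = mkSeg(dfCols),
    afMetrics = .segmentMetrics(values[, afCols, drop = FALSE], layout),
    dfMetrics = .segmentMetrics(values[, dfCols, drop = FALSE], layout),
    splitMs = tMs[zc]
  )
}
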