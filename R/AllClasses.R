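#' @import methods
NULL

#' ProbeLayout: geometry of a high-density probe
#'
#' Channel positions on the probe shank (micrometres), the
#' analog-to-digital converter (ADC) each channel belongs to, and the
#' channel's sampling rank within its ADC.  Channels of one ADC are
#' multiplexed sequentially, so a channel of rank r is acquired
#' r x 2.78 microseconds after its group's first channel; this
#' sub-sample stagger is what [correctAdcOffsets()] undoes.
#'
#' @slot positions numeric matrix, channels x 2 (columns `x`, `y` in um).
#'   y increases away from the probe tip; channel indices are 1-based in R.
#' @slot adcGroup integer vector, ADC group index per channel (1-based).
#' @slot adcRank integer vector, sampling order within the ADC group
#'   (0-based; rank 0 has no stagger).
#' @slot verticalPitch numeric, row pitch in um.
#' @slot nColumns integer, number of electrode columns.
#' @slot preset character, name of the generating preset.
#'
#' @seealso [makeProbeLayout()], [pairDistance()]
#' @export
setClass("ProbeLayout",
  representation(
    positions = "matrix",
    adcGroup = "integer",
    adcRank = "integer",
    verticalPitch = "numeric",
    nColumns = "integer",
    preset = "character"
  )
)

setValidity("ProbeLayout", function(object) {
  n <- nrow(object@positions)
  msg <- character()
  if (n < 2L) msg <- c(msg, "a probe needs at least 2 channels")
  if (ncol(object@positions) != 2L) msg <- c(msg, "positions must be n x 2")
  if (anyDuplicated(object@positions)) msg <- c(msg, "channel positions must be distinct")
  if (length(object@adcGroup) != n || length(object@adcRank) != n)
    msg <- c(msg, "adcGroup/adcRank length must match channel count")
  if (any(object@adcRank < 0L)) msg <- c(msg, "adcRank must be >= 0")
  if (length(msg)) msg else TRUE
})

#' RawRecording: spike-band multichannel recording
#'
#' Samples are held in microvolts (int16 counts times gain).  The binary
#' on-disk form is frame-interleaved little-endian int16; see
#' [writeRawRecording()].
#'
#' @slot samples numeric matrix, channels x time, in uV.
#' @slot samplingRate numeric, Hz.
#' @slot gainUv numeric, uV per int16 count (quantization step on disk).
#' @slot layout a [ProbeLayout-class].
#' @export
setClass("RawRecording",
  representation(
    samples = "matrix",
    samplingRate = "numeric",
    gainUv = "numeric",
    layout = "ProbeLayout"
  )
)

setValidity("RawRecording", function(object) {
  msg <- character()
  if (nrow(object@samples) != nChannels(object@layout))
    msg <- c(msg, "sample rows must match layout channel count")
  if (object@gainUv <= 0) msg <- c(msg, "gain must be > 0")
  if (object@samplingRate <= 0) msg <- c(msg, "sampling rate must be > 0")
  if (length(msg)) msg else TRUE
})

#' SortedUnits: spike-sorted unit container
#'
#' Per-unit spike-time vectors (seconds, sorted ascending) together with a
#' unit table carrying peak channel, class label (`"TCA"`, `"V1N"` or
#' `"unclassified"`) and mean firing rate.  Consumes spike-sorter output;
#' sorting itself is out of scope.
#'
#' @slot spikes named list of numeric vectors, spike times in seconds.
#' @slot units data.frame with columns `unit_id`, `peak_channel`, `label`,
#'   `firing_rate_hz`.
#' @slot duration numeric, recording duration in seconds.
#' @export
setClass("SortedUnits",
  representation(
    spikes = "list",
    units = "data.frame",
    duration = "numeric"
  )
)

setValidity("SortedUnits", function(object) {
  msg <- character()
  ids <- object@units$unit_id
  if (anyDuplicated(ids)) msg <- c(msg, "unit ids must be unique")
  if (!identical(sort(names(object@spikes)), sort(as.character(ids))))
    msg <- c(msg, "spike list names must match unit table ids")
  for (id in names(object@spikes)) {
    st <- object@spikes[[id]]
    if (is.unsorted(st)) msg <- c(msg, sprintf("unit %s: spike times not sorted", id))
    if (length(st) && (min(st) < 0 || max(st) >= object@duration))
      msg <- c(msg, sprintf("unit %s: spike times outside [0, duration)", id))
  }
  ok <- object@units$label %in% c("TCA", "V1N", "unclassified")
  if (!all(ok)) msg <- c(msg, "labels must be TCA, V1N or unclassified")
  if (length(msg)) msg else TRUE
})

#' MultiChannelWaveform: spike-triggered average across all channels
#'
#' The mean spike-band snippet over a peri-spike window for one unit,
#' channels x time in uV, after ADC sample-time correction.
#'
#' @slot values numeric matrix, channels x time (uV).
#' @slot windowMs numeric length 2, window relative to the spike trough
#'   (ms), e.g. `c(-5, 5)`.
#' @slot samplingRate numeric, Hz.
#' @slot nSpikesUsed integer, snippets averaged.
#' @slot peakChannel integer, channel with the largest |trough|.
#' @export
setClass("MultiChannelWaveform",
  representation(
    values = "matrix",
    windowMs = "numeric",
    samplingRate = "numeric",
    nSpikesUsed = "integer",
    peakChannel = "integer"
  )
)

setValidity("MultiChannelWaveform", function(object) {
  msg <- character()
  if (length(object@windowMs) != 2L || object@windowMs[1] >= object@windowMs[2])
    msg <- c(msg, "windowMs must be (pre, post) with pre < post")
  if (object@nSpikesUsed < 1L) msg <- c(msg, "nSpikesUsed must be >= 1")
  nt <- round(diff(object@windowMs) / 1000 * object@samplingRate) + 1L
  if (abs(ncol(object@values) - nt) > 1L)
    msg <- c(msg, "time axis inconsistent with window and sampling rate")
  if (object@peakChannel < 1L || object@peakChannel > nrow(object@values))
    msg <- c(msg, "peakChannel out of range")
  if (length(msg)) msg else TRUE
})

#' CorrectedCCG: jitter-corrected cross-correlogram
#'
#' Lag-binned coincidence counts of post-minus-pre spike-time differences,
#' together with the mean over jitter surrogates (spike times randomized
#' within fixed 10 ms wall-clock windows).  The corrected CCG is
#' `raw - jitterMean` exactly; its baseline SD is measured over lags in
#' \[-4.5, 0.5\] ms.
#'
#' @slot lagsMs numeric, bin centers (ms), half-open bins \[lo, hi).
#' @slot rawCounts numeric, raw counts per bin.
#' @slot jitterMean numeric, per-bin mean over surrogates.
#' @slot binMs numeric, bin width (ms).
#' @slot jitterWindowMs numeric, jitter window width (ms).
#' @slot nPre,nPost integer, spike counts of the two trains.
#' @export
setClass("CorrectedCCG",
  representation(
    lagsMs = "numeric",
    rawCounts = "numeric",
    jitterMean = "numeric",
    binMs = "numeric",
    jitterWindowMs = "numeric",
    nPre = "integer",
    nPost = "integer"
  )
)

setValidity("CorrectedCCG", function(object) {
  msg <- character()
  nb <- length(object@lagsMs)
  if (length(object@rawCounts) != nb || length(object@jitterMean) != nb)
    msg <- c(msg, "rawCounts/jitterMean must match lag bins")
  if (object@binMs <= 0) msg <- c(msg, "binMs must be > 0")
  if (min(object@lagsMs) > -4.5 || max(object@lagsMs) < 0.5)
    msg <- c(msg, "lag range must cover the baseline window [-4.5, 0.5] ms")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: simulator bookkeeping for recovery tests
#'
#' @slot connections data.frame with columns `pre_id`, `post_id`, `prob`,
#'   `delay_ms`, `jitter_sd_ms`.
#' @slot templates named list of template specifications
#'   (see [templateSpec()]).
#' @slot transmitted named list (one element per connection,
#'   `"pre->post"`): logical vector over presynaptic spikes, TRUE where
#'   the spike triggered an extra postsynaptic spike.
#' @export
setClass("GroundTruth",
  representation(
    connections = "data.frame",
    templates = "list",
    transmitted = "list"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  cn <- object@connections
  if (nrow(cn)) {
    if (any(cn$prob <= 0 | cn$prob > 1)) msg <- c(msg, "transmission prob must be in (0, 1]")
    if (any(cn$delay_ms <= 0)) msg <- c(msg, "connection delay must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' StaMap: spike-triggered average of a postsynaptic probe
#'
#' Average spike-band signal of a (second) probe triggered on presynaptic
#' spike times, after exclusion of triggers near postsynaptic spikes.
#'
#' @slot values numeric matrix, channels x lag (uV).
#' @slot lagsMs numeric, lag axis (ms), spanning at least \[-5, +10\].
#' @slot samplingRate numeric, Hz.
#' @slot nSpikesUsed integer, triggers averaged (<= 20000 by default).
#' @slot excludedSpikes integer, triggers dropped by the +/-1 ms exclusion.
#' @slot triggerTimes numeric, the trigger times actually used (seconds).
#' @export
setClass("StaMap",
  representation(
    values = "matrix",
    lagsMs = "numeric",
    samplingRate = "numeric",
    nSpikesUsed = "integer",
    excludedSpikes = "integer",
    triggerTimes = "numeric"
  )
)

setValidity("StaMap", function(object) {
  msg <- character()
  if (length(object@lagsMs) != ncol(object@values))
    msg <- c(msg, "lag axis must match value columns")
  if (object@nSpikesUsed < 1L) msg <- c(msg, "nSpikesUsed must be >= 1")
  if (length(msg)) msg else TRUE
})
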