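#' Number of channels
#' @param x a [ProbeLayout-class] or [RawRecording-class]
#' @return integer
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Channel positions in micrometres
#' @param x a [ProbeLayout-class]
#' @return numeric matrix, channels x 2 (`x`, `y`)
#' @export
setGeneric("channelPositions", function(x) standardGeneric("channelPositions"))

#' ADC sampling rank per channel (0-based)
#' @param x a [ProbeLayout-class]
#' @return integer vector
#' @export
setGeneric("adcRank", function(x) standardGeneric("adcRank"))

#' Sampling rate in Hz
#' @param x a [RawRecording-class], [MultiChannelWaveform-class] or [StaMap-class]
#' @return numeric
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Recording duration in seconds
#' @param x a [RawRecording-class] or [SortedUnits-class]
#' @return numeric
#' @export
setGeneric("durationS", function(x) standardGeneric("durationS"))

#' Spike times of one unit (seconds)
#' @param x a [SortedUnits-class]
#' @param unit unit id (coerced to character)
#' @return numeric vector
#' @export
setGeneric("spikeTimes", function(x, unit) standardGeneric("spikeTimes"))

#' Unit table (id, peak channel, label, firing rate)
#' @param x a [SortedUnits-class]
#' @return data.frame
#' @export
setGeneric("unitTable", function(x) standardGeneric("unitTable"))

#' Unit ids
#' @param x a [SortedUnits-class] or [GroundTruth-class]
#' @return character vector
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))

#' Waveform/STA values matrix (channels x time, uV)
#' @param x a [MultiChannelWaveform-class] or [StaMap-class]
#' @return numeric matrix
#' @export
setGeneric("waveformValues", function(x) standardGeneric("waveformValues"))

#' Peak channel (largest |trough|)
#' @param x a [MultiChannelWaveform-class]
#' @return integer
#' @export
setGeneric("peakChannel", function(x) standardGeneric("peakChannel"))

#' Time axis of a waveform (ms relative to the spike)
#' @param x a [MultiChannelWaveform-class] or [StaMap-class]
#' @return numeric vector
#' @export
setGeneric("timesMs", function(x) standardGeneric("timesMs"))

#' Jitter-corrected CCG counts (raw minus surrogate mean)
#' @param x a [CorrectedCCG-class]
#' @return numeric vector, one value per lag bin
#' @export
setGeneric("correctedCounts", function(x) standardGeneric("correctedCounts"))

#' Raw CCG counts
#' @param x a [CorrectedCCG-class]
#' @return numeric vector
#' @export
setGeneric("rawCounts", function(x) standardGeneric("rawCounts"))

#' CCG lag bin centers (ms)
#' @param x a [CorrectedCCG-class]
#' @return numeric vector
#' @export
setGeneric("lagsMs", function(x) standardGeneric("lagsMs"))

#' Baseline SD of the corrected CCG over lags in [-4.5, 0.5] ms
#' @param x a [CorrectedCCG-class]
#' @return numeric
#' @export
setGeneric("baselineSd", function(x) standardGeneric("baselineSd"))

#' Ground-truth connection list
#' @param x a [GroundTruth-class]
#' @return data.frame
#' @export
setGeneric("trueConnections", function(x) standardGeneric("trueConnections"))

#' Per-presynaptic-spike transmission flags of one connection
#' @param x a [GroundTruth-class]
#' @param pre,post unit ids
#' @return logical vector over presynaptic spikes
#' @export
setGeneric("transmittedFlags", function(x, pre, post) standardGeneric("transmittedFlags"))
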