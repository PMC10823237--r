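#' Template specification for the recording simulator
#'
#' Describes a somatic or axonal multichannel template.  Somata are
#' compact biphasic waveforms (narrow negative trough, small positive
#' overshoot well under 1 ms) so they never satisfy the axon rebound
#' criterion.  Axons carry an early narrow axonal field (AF) at the peak
#' channel followed by a broad positive rebound -- the dendritic/synaptic
#' contact field (DF) -- whose duration at half height is `reboundMs` and
#' whose spatial center sits `afDfOffsetRows` rows away.  With a finite
#' `conductionSpeed` a propagating spikelet runs along the peak channel's
#' column toward the tip, shifting per-channel peak times by
#' (vertical distance)/speed.
#'
#' Default amplitudes are the reported population means for cortical
#' somata (-54.9/+24.6 uV) and thalamocortical AF (-26.1/+12.8 uV) and
#' DF (-12.5/+12.1 uV), placing fixtures in the realistic regime.
#'
#' @param kind `"soma"` or `"axon"`.
#' @param peakChannel 1-based channel index of the trough.
#' @param negAmpUv,posAmpUv trough and overshoot amplitude (uV) of the
#'   somatic waveform, or of the AF for axons.  `negAmpUv <= 0 <= posAmpUv`.
#' @param spreadChannels number of channels whose peak-to-peak profile
#'   exceeds 0.1 of the maximum (exact by construction).
#' @param dfNegAmpUv,dfPosAmpUv DF trailing trough and rebound amplitude
#'   (uV), axons only.
#' @param dfSpreadChannels DF spatial spread in channels (axons; defaults
#'   to `spreadChannels + 4`, DF broader than AF as observed).
#' @param reboundMs DF rebound duration at half height (ms), axons only.
#' @param conductionSpeed propagation speed in m/s, or `NA` for none.
#' @param afDfOffsetRows vertical offset of the DF center, in rows.
#' @return a list of class `"templateSpec"`
#' @seealso [makeTemplate()]
#' @export
templateSpec <- function(kind = c("soma", "axon"), peakChannel,
                         negAmpUv = if (kind == "axon") -26.1 else -54.9,
                         posAmpUv = if (kind == "axon") 12.8 else 24.6,
                         spreadChannels = 8L,
                         dfNegAmpUv = -12.5, dfPosAmpUv = 12.1,
                         dfSpreadChannels = spreadChannels + 4L,
                         reboundMs = 1.5, conductionSpeed = NA_real_,
                         afDfOffsetRows = 1L) {
  kind <- match.arg(kind)
  if (negAmpUv > 0 || posAmpUv < 0)
    stop("invalid-argument: need negAmpUv <= 0 <= posAmpUv")
  if (spreadChannels < 1L) stop("invalid-argument: spreadChannels must be >= 1")
  if (kind == "axon" && reboundMs < 0)
    stop("invalid-argument: reboundMs must be >= 0")
  structure(list(
    kind = kind, peakChannel = as.integer(peakChannel),
    negAmpUv = negAmpUv, posAmpUv = posAmpUv,
    spreadChannels = as.integer(spreadChannels),
    dfNegAmpUv = dfNegAmpUv, dfPosAmpUv = dfPosAmpUv,
    dfSpreadChannels = as.integer(dfSpreadChannels),
    reboundMs = reboundMs, conductionSpeed = conductionSpeed,
    afDfOffsetRows = as.integer(afDfOffsetRows)
  ), class = "templateSpec")
}

# Gaussian spatial sigma such that exactly k of the distances d yield
# weights exp(-d^2/(2 sigma^2)) > 0.1.  Ties broken by index epsilon.
.spreadSigma <- function(d, k) {
  n <- length(d)
  if (k > n) stop("invalid-argument: spread larger than probe span")
  ds <- sort(d)
  cut <- if (k == n) ds[n] * 1.05 + 1e-9 else (ds[k] + ds[k + 1]) / 2
  cut / sqrt(2 * log(10))
}

.gaussT <- function(t, mu, sigma) exp(-((t - mu)^2) / (2 * sigma^2))

# column index (1-based) of each channel
.channelColumn <- function(layout) {
  (seq_len(nChannels(layout)) - 1L) %% layout@nColumns + 1L
}

#' Render a multichannel template from its specification
#'
#' Produces the noise-free spike-triggered waveform a unit of the given
#' specification would leave on the probe, on the recording's time grid
#' with the trough at t = 0.  Amplitude decay over channels is Gaussian
#' in distance, calibrated so that exactly `spreadChannels` channels
#' exceed 0.1 of the peak-normalized peak-to-peak profile (likewise
#' `dfSpreadChannels` for the DF taken alone).
#'
#' @param spec a [templateSpec()].
#' @param layout a [ProbeLayout-class].
#' @param windowMs length-2 window around the spike, ms.
#' @param samplingRate Hz.
#' @return a [MultiChannelWaveform-class]
#' @export
makeTemplate <- function(spec, layout, windowMs = c(-5, 5), samplingRate = 30000) {
  stopifnot(inherits(spec, "templateSpec"))
  n <- nChannels(layout)
  if (spec$peakChannel < 1L || spec$peakChannel > n)
    stop("invalid-argument: peak channel outside the layout")
  tMs <- seq(windowMs[1], windowMs[2], by = 1000 / samplingRate)
  pos <- channelPositions(layout)
  dPeak <- sqrt(rowSums((pos - matrix(pos[spec$peakChannel, ], n, 2, byrow = TRUE))^2))
  dPeak <- dPeak + seq_len(n) * 1e-9  # tie-break
  wAf <- exp(-dPeak^2 / (2 * .spreadSigma(dPeak, spec$spreadChannels)^2))

  if (spec$kind == "soma") {
    tc <- spec$negAmpUv * .gaussT(tMs, 0, 0.10) +
      spec$posAmpUv * .gaussT(tMs, 0.5, 0.12)
    values <- outer(wAf, tc)
  } else {
    # AF: narrow trough, damped overshoot, small trailing undershoot so the
    # waveform returns below zero before the DF rebound rises
    af <- spec$negAmpUv * .gaussT(tMs, 0, 0.08) +
      0.3 * spec$posAmpUv * .gaussT(tMs, 0.25, 0.08) +
      0.15 * spec$negAmpUv * .gaussT(tMs, 0.55, 0.15)
    tDf <- 0.6 + spec$reboundMs
    sigDf <- max(spec$reboundMs, 1e-3) / (2 * sqrt(2 * log(2)))  # FWHM = reboundMs
    df <- spec$dfPosAmpUv * .gaussT(tMs, tDf, sigDf) +
      spec$dfNegAmpUv * 0.4 * .gaussT(tMs, tDf + spec$reboundMs, 0.3)
    dfCenter <- pos[spec$peakChannel, ] +
      c(0, spec$afDfOffsetRows * layout@verticalPitch)
    dDf <- sqrt(rowSums((pos - matrix(dfCenter, n, 2, byrow = TRUE))^2))
    dDf <- dDf + seq_len(n) * 1e-9
    wDf <- exp(-dDf^2 / (2 * .spreadSigma(dDf, spec$dfSpreadChannels)^2))
    wDf <- wDf / max(wDf)
    values <- outer(wAf, af) + outer(wDf, df)

    if (is.finite(spec$conductionSpeed) && spec$conductionSpeed > 0) {
      # propagating spikelet along the peak channel's column toward the tip
      colId <- .channelColumn(layout)
      yPeak <- pos[spec$peakChannel, "y"]
      onPath <- colId == colId[spec$peakChannel] & pos[, "y"] < yPeak
      tArr <- -(yPeak - pos[, "y"]) / (spec$conductionSpeed * 1000)  # ms
      usable <- onPath & tArr >= windowMs[1] + 0.3
      for (ch in which(usable)) {
        values[ch, ] <- values[ch, ] +
          0.5 * spec$negAmpUv * .gaussT(tMs, tArr[ch], 0.08)
      }
    }
  }

  new("MultiChannelWaveform", values = values, windowMs = as.numeric(windowMs),
      samplingRate = samplingRate, nSpikesUsed = 1L,
      peakChannel = spec$peakChannel)
}

#' @rdname waveformValues
setMethod("waveformValues", "MultiChannelWaveform", function(x) x@values)

#' @rdname peakChannel
setMethod("peakChannel", "MultiChannelWaveform", function(x) x@peakChannel)

#' @rdname samplingRate
setMethod("samplingRate", "MultiChannelWaveform", function(x) x@samplingRate)

#' @rdname timesMs
setMethod("timesMs", "MultiChannelWaveform", function(x)
  seq(x@windowMs[1], x@windowMs[2], by = 1000 / x@samplingRate))

setMethod("show", "MultiChannelWaveform", function(object) {
  cat(sprintf(
    "MultiChannelWaveform: %d channels x %d samples, window [%g, %g] ms, %d spikes, peak ch %d\n",
    nrow(object@values), ncol(object@values), object@windowMs[1],
    object@windowMs[2], object@nSpikesUsed, object@peakChannel))
})
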