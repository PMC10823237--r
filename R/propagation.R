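#' Estimate axonal propagation speed from an MCW
#'
#' When the probe is aligned with an axonal path, the action-potential
#' peak arrives at successive channels of a column with a fixed delay
#' per unit distance.  Per column, the AP peak time is detected on each
#' usable channel -- channels at least `marginPeak` channels (in-column)
#' away from the peak channel's row and `marginTip` channels from the
#' tip -- as the time of the largest |amplitude| within the peak window,
#' provided that amplitude exceeds `sdMult` (default 4) SDs of that
#' channel's baseline window.  A line is fitted to peak time versus
#' vertical distance; columns with |correlation| above `rThresh`
#' (default 0.725) qualify, and the best-correlated column's slope gives
#' the speed in m/s.  `NULL` is returned when no column qualifies (e.g.
#' simultaneous peaks, or noise-dominated fits).
#'
#' @param mcw a [MultiChannelWaveform-class]; its window must reach -5 ms
#'   for the baseline.
#' @param layout the matching [ProbeLayout-class].
#' @param peakWindowMs window searched for the AP peak (ms).
#' @param baselineWindowMs window measuring the per-channel baseline SD.
#' @param sdMult amplitude threshold in baseline SDs.
#' @param rThresh minimum |correlation| of the linear fit.
#' @param marginPeak,marginTip usable-channel margins (in-column channels).
#' @param minUsable minimum usable channels per column.
#' @return speed in m/s, or `NULL`
#' @export
estimatePropagationSpeed <- function(mcw, layout,
                                     peakWindowMs = c(-2.5, -0.1),
                                     baselineWindowMs = c(-5, -2.5),
                                     sdMult = 4, rThresh = 0.725,
                                     marginPeak = 5L, marginTip = 5L,
                                     minUsable = 5L) {
  if (mcw@windowMs[1] > baselineWindowMs[1])
    stop("invalid-argument: MCW window too short for the baseline (needs -5 ms)")
  values <- waveformValues(mcw)
  tMs <- timesMs(mcw)
  baseIdx <- which(tMs >= baselineWindowMs[1] & tMs < baselineWindowMs[2])
  peakIdx <- which(tMs >= peakWindowMs[1] & tMs <= peakWindowMs[2])
  y <- channelPositions(layout)[, "y"]
  colId <- .channelColumn(layout)
  yPeak <- y[peakChannel(mcw)]

  best <- NULL
  bestR <- -Inf
  for (cc in unique(colId)) {
    chs <- which(colId == cc)
    chs <- chs[order(y[chs])]
    inColIdx <- seq_along(chs)
    peakPos <- which.min(abs(y[chs] - yPeak))
    usable <- chs[inColIdx > marginTip & abs(inColIdx - peakPos) >= marginPeak]
    if (length(usable) < minUsable) next

    ts <- ys <- numeric(0)
    for (ch in usable) {
      sdB <- max(stats::sd(values[ch, baseIdx]), 1e-9)
      w <- values[ch, peakIdx]
      pk <- which.max(abs(w))
      # a maximum at the window edge is a clipped peak, not an AP arrival
      if (abs(w[pk]) >= sdMult * sdB && pk > 1L && pk < length(w)) {
        ts <- c(ts, tMs[peakIdx][pk])
        ys <- c(ys, y[ch])
      }
    }
    if (length(ts) < minUsable) next
    if (stats::sd(ts) == 0) next  # simultaneous peaks: no finite speed
    r <- stats::cor(ys, ts)
    if (!is.finite(r) || abs(r) < rThresh) next
    slope <- stats::coef(stats::lm(ts ~ ys))[2]  # ms per um
    if (!is.finite(slope) || slope == 0) next
    if (abs(r) > bestR) {
      bestR <- abs(r)
      best <- 1 / (abs(slope) * 1000)  # um/ms -> m/s
    }
  }
  if (is.null(best)) NULL else unname(best)
}
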