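# Band-limited fractional delay of a sampled trace via FFT phase shift.
# shift > 0 delays (moves features to later samples); sub-sample shifts
# are exact for band-limited content, which is why per-ADC stagger is
# realized this way rather than by integer sample moves.
.fftDelay <- function(x, shift) {
  if (shift == 0) return(x)
  n <- length(x)
  npad <- 2^ceiling(log2(n + 128))
  xp <- c(x, rep(0, npad - n))
  k <- c(0:(npad / 2), -(npad / 2 - 1):-1) / npad
  ph <- exp(-2i * pi * k * shift)
  ph[npad / 2 + 1] <- cos(pi * shift)  # keep Nyquist bin real
  y <- Re(stats::fft(stats::fft(xp) * ph, inverse = TRUE)) / npad
  y[seq_len(n)]
}

# Apply per-channel ADC acquisition stagger to a channels x time matrix.
# direction +1 = as acquired (rank r delayed by r x staggerUs),
# direction -1 = correction (advance), see correctAdcOffsets().
.adcShift <- function(values, layout, samplingRate, direction,
                      staggerUs = 2.78) {
  rk <- adcRank(layout)
  for (ch in seq_len(nrow(values))) {
    sh <- direction * rk[ch] * staggerUs * 1e-6 * samplingRate
    if (sh != 0) values[ch, ] <- .fftDelay(values[ch, ], sh)
  }
  values
}

#' Render a raw recording from spike trains and templates
#'
#' Linear superposition of each unit's template at each of its spike
#' times, with the per-ADC acquisition stagger (adcRank x 2.78 us,
#' applied by band-limited resampling) and additive i.i.d. Gaussian
#' noise.  Values are kept in uV; quantization to int16 happens on
#' [writeRawRecording()].  Deterministic for a fixed seed.
#'
#' @param units a [SortedUnits-class].
#' @param templates named list of [templateSpec()] (names = unit ids), or
#'   a [GroundTruth-class] whose `templates` slot is populated.  Units
#'   without a template contribute no signal.
#' @param layout a [ProbeLayout-class].
#' @param noiseSdUv Gaussian noise SD in uV (0 disables).
#' @param seed integer seed for the noise.
#' @param samplingRate Hz.
#' @param gainUv uV per int16 count carried into the recording metadata.
#' @param staggerUs per-rank ADC stagger in us.
#' @return a [RawRecording-class]
#' @export
renderRecording <- function(units, templates, layout, noiseSdUv = 0, seed = 1,
                            samplingRate = 30000, gainUv = 0.195,
                            staggerUs = 2.78) {
  if (is(templates, "GroundTruth")) templates <- templates@templates
  dur <- durationS(units)
  nSamp <- as.integer(round(dur * samplingRate))
  nCh <- nChannels(layout)
  out <- matrix(0, nCh, nSamp)

  for (id in names(templates)) {
    st <- spikeTimes(units, id)
    if (!length(st)) next
    if (any(st < 0 | st >= dur))
      stop("invalid-argument: spike beyond recording duration for unit ", id)
    tmpl <- makeTemplate(templates[[id]], layout, samplingRate = samplingRate)
    tv <- .adcShift(tmpl@values, layout, samplingRate, direction = +1,
                    staggerUs = staggerUs)
    preSamp <- round(-tmpl@windowMs[1] / 1000 * samplingRate)
    lt <- ncol(tv)
    centers <- round(st * samplingRate) + 1L
    for (c0 in centers) {
      i0 <- c0 - preSamp
      i1 <- i0 + lt - 1L
      j0 <- max(1L, i0); j1 <- min(nSamp, i1)
      if (j0 > j1) next
      out[, j0:j1] <- out[, j0:j1] + tv[, (j0 - i0 + 1L):(j1 - i0 + 1L)]
    }
  }

  if (noiseSdUv > 0) {
    set.seed(as.integer(seed))
    out <- out + matrix(stats::rnorm(nCh * nSamp, 0, noiseSdUv), nCh, nSamp)
  }
  rawRecording(out, layout, samplingRate = samplingRate, gainUv = gainUv)
}

#' Attach ground-truth templates
#'
#' @param truth a [GroundTruth-class]
#' @param templates named list of [templateSpec()]
#' @return the modified [GroundTruth-class]
#' @export
setTemplates <- function(truth, templates) {
  stopifnot(is(truth, "GroundTruth"))
  truth@templates <- templates
  truth
}
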