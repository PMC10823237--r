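test_that("MCW averaging suppresses noise as sigma/sqrt(N)", {
  lay <- makeProbeLayout(8)
  spec <- templateSpec("soma", peakChannel = 4, spreadChannels = 4)
  tmpl <- waveformValues(makeTemplate(spec, lay))
  resid <- sapply(1:3, function(s) {
    mcw <- noisyMcw(spec, lay, nSpikes = 200, noiseSdUv = 5, seed = s)
    sqrt(mean((waveformValues(mcw) - tmpl)^2))
  })
  expected <- 5 / sqrt(200)
  expect_lt(abs(mean(resid) - expected) / expected, 0.2)
})

test_that("spike caps produce a seed-deterministic subsample", {
  lay <- makeProbeLayout(8)
  spec <- templateSpec("soma", peakChannel = 4, spreadChannels = 4)
  st <- seq(0.05, by = 0.011, length.out = 300)
  units <- sortedUnits(list(u = st), duration = max(st) + 0.05)
  rec <- renderRecording(units, list(u = spec), lay, noiseSdUv = 2, seed = 1)
  m1 <- extractMcw(rec, st, maxSpikes = 100, seed = 42)
  m2 <- extractMcw(rec, st, maxSpikes = 100, seed = 42)
  expect_equal(m1@nSpikesUsed, 100L)
  expect_identical(waveformValues(m1), waveformValues(m2))
  expect_equal(extractMcw(rec, st, seed = 1)@nSpikesUsed, 300L)
  expect_error(extractMcw(rec, numeric(0)), "empty-input")
})

test_that("ADC offset correction aligns a staggered common sine to < 0.5 us", {
  lay <- makeProbeLayout(12, adcGroupSize = 12L)  # ranks 0..11
  fs <- 30000
  t <- seq(0, 0.1, by = 1 / fs)
  # acquisition convention: a channel of rank r appears delayed by
  # r x 2.78 us on the nominal grid; correction advances it back
  stag <- t(sapply(adcRank(lay), function(r) sin(2 * pi * 1000 * (t - r * 2.78e-6))))
  corr <- correctAdcOffsets(stag, lay, samplingRate = fs)
  # residual per-channel lag from the phase of the 1 kHz component
  phase <- apply(corr[, 300:2700], 1, function(v) {
    tt <- t[300:2700]
    atan2(sum(v * cos(2 * pi * 1000 * tt)), sum(v * sin(2 * pi * 1000 * tt)))
  })
  lagUs <- (phase - phase[1]) / (2 * pi * 1000) * 1e6
  expect_lt(max(abs(lagUs)), 0.5)

  # all ranks zero: identity
  lay0 <- makeProbeLayout(12, adcGroupSize = 1L)
  x <- matrix(rnorm(12 * 500), 12)
  expect_equal(correctAdcOffsets(x, lay0), x)
})

test_that("stagger followed by correction recovers the original band-limited trace", {
  lay <- makeProbeLayout(12, adcGroupSize = 12L)
  fs <- 30000
  t <- seq(0, 0.05, by = 1 / fs)
  base <- function(tt) sin(2 * pi * 800 * tt) + 0.5 * cos(2 * pi * 2100 * tt)
  clean <- t(sapply(adcRank(lay), function(r) base(t)))
  stag <- t(sapply(adcRank(lay), function(r) base(t - r * 2.78e-6)))
  corr <- correctAdcOffsets(stag, lay, samplingRate = fs)
  mid <- 100:1400  # away from the window edges
  rms <- sqrt(mean((corr[, mid] - clean[, mid])^2))
  expect_lt(rms, 0.01 * max(abs(clean)))
})

test_that("spread counts supra-threshold channels exactly as constructed", {
  lay <- makeProbeLayout(96)
  m30 <- waveformMetrics(makeTemplate(templateSpec("soma", peakChannel = 48,
                                                   spreadChannels = 30), lay), lay)
  expect_equal(m30$spreadChannels, 30L)
  m1 <- waveformMetrics(makeTemplate(templateSpec("soma", peakChannel = 48,
                                                  spreadChannels = 1), lay), lay)
  expect_equal(m1$spreadChannels, 1L)
  expect_equal(m1$spreadUm, 20)  # single row occupies one pitch

  zero <- makeTemplate(templateSpec("soma", peakChannel = 48, negAmpUv = 0,
                                    posAmpUv = 0), lay)
  expect_error(waveformMetrics(zero, lay), "degenerate-waveform")
})

test_that("somatic fixture amplitudes are recovered at the peak channel", {
  lay <- makeProbeLayout(64)
  m <- waveformMetrics(makeTemplate(templateSpec("soma", peakChannel = 32,
                                                 negAmpUv = -54.9, posAmpUv = 24.6,
                                                 spreadChannels = 8), lay), lay)
  expect_equal(m$negPeakUv, -54.9, tolerance = 0.01)
  expect_equal(m$posPeakUv, 24.6, tolerance = 0.01)
  expect_lt(m$reboundDurationMs, 1)
})

test_that("classification follows the rebound duration and spread rule", {
  lay <- makeProbeLayout(64)
  ax <- waveformMetrics(makeTemplate(templateSpec("axon", peakChannel = 32,
    spreadChannels = 12, dfSpreadChannels = 15, reboundMs = 1.5), lay), lay)
  expect_gt(ax$reboundDurationMs, 1)
  expect_gt(ax$reboundSpreadChannels, 10)
  expect_equal(classifyUnit(ax), "TCA")

  so <- waveformMetrics(makeTemplate(templateSpec("soma", peakChannel = 32,
    spreadChannels = 8), lay), lay)
  expect_equal(classifyUnit(so), "V1N")

  # long rebound but sub-threshold spread: not an axon
  nr <- waveformMetrics(makeTemplate(templateSpec("axon", peakChannel = 32,
    spreadChannels = 6, dfSpreadChannels = 8, reboundMs = 1.5), lay), lay)
  expect_false(classifyUnit(nr) == "TCA")

  # sub-threshold amplitude: unclassified
  weak <- waveformMetrics(makeTemplate(templateSpec("soma", peakChannel = 32,
    negAmpUv = -4, posAmpUv = 2, spreadChannels = 8), lay), lay)
  expect_equal(classifyUnit(weak), "unclassified")
})

test_that("AF/DF decomposition isolates trough and rebound with DF spreading wider", {
  lay <- makeProbeLayout(96)
  tm <- makeTemplate(templateSpec("axon", peakChannel = 48, spreadChannels = 12,
                                  dfSpreadChannels = 20, reboundMs = 1.5), lay)
  sp <- splitAfDf(tm, lay)
  expect_equal(sp$afMetrics$negPeakUv, -26.1, tolerance = 0.5)
  expect_equal(sp$dfMetrics$posPeakUv, 12.1, tolerance = 0.5)
  expect_gt(sp$dfMetrics$spreadChannels, sp$afMetrics$spreadChannels)
  expect_gt(sp$dfMetrics$spreadUm, sp$afMetrics$spreadUm)
  expect_error(splitAfDf(tm, lay, label = "V1N"), "refused")
})

test_that("propagation speed is recovered without bias across planted speeds", {
  lay <- makeProbeLayout(96)
  for (speed in c(0.3, 0.92, 2.0)) {
    errs <- sapply(1:10, function(s) {
      tm <- makeTemplate(templateSpec("axon", peakChannel = 95,
                                      spreadChannels = 12,
                                      conductionSpeed = speed), lay)
      set.seed(s)
      tm@values <- tm@values + matrix(rnorm(length(tm@values), 0, 0.3),
                                      nrow(tm@values))
      est <- estimatePropagationSpeed(tm, lay)
      if (is.null(est)) NA_real_ else abs(est - speed) / speed
    })
    expect_lt(median(errs, na.rm = TRUE), 0.1)
  }
})

test_that("degenerate propagation inputs yield no speed", {
  lay <- makeProbeLayout(96)
  # simultaneous peaks on all channels: infinite-slope fit rejected
  tm <- makeTemplate(templateSpec("axon", peakChannel = 95, spreadChannels = 12), lay)
  set.seed(1)
  tm@values <- matrix(rnorm(length(tm@values), 0, 0.2), nrow(tm@values))
  tm@values[, 100] <- tm@values[, 100] - 20
  expect_null(estimatePropagationSpeed(tm, lay))

  # noise-dominated channels: correlation below threshold
  tm2 <- makeTemplate(templateSpec("axon", peakChannel = 95, spreadChannels = 12), lay)
  set.seed(2)
  tm2@values <- tm2@values + matrix(rnorm(length(tm2@values), 0, 10),
                                    nrow(tm2@values))
  expect_null(estimatePropagationSpeed(tm2, lay))

  short <- new("MultiChannelWaveform",
               values = waveformValues(tm2)[, 61:240, drop = FALSE],
               windowMs = c(-3, 2.9666667), samplingRate = 30000,
               nSpikesUsed = 1L, peakChannel = 95L)
  expect_error(estimatePropagationSpeed(short, lay), "invalid-argument")
})
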