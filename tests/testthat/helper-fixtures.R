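# Shared fixture builders (everything generated in code; no stored data).

# Recording with a synaptic footprint injected at pre-spike times:
# a narrow negative blip on `channels`, `lagMs` after each trigger.
# Used by the STA tests; returns the recording and the trigger times.
footprintRecording <- function(nTriggers, footprints, layout, noiseSdUv = 10,
                               fs = 30000, seed = 1, spacingS = 0.006) {
  set.seed(seed)
  trig <- seq(0.05, by = spacingS, length.out = nTriggers) +
    stats::runif(nTriggers, 0, 0.002)
  durS <- max(trig) + 0.05
  nSamp <- ceiling(durS * fs)
  nCh <- nChannels(layout)
  mat <- matrix(stats::rnorm(nCh * nSamp, 0, noiseSdUv), nCh)
  # 0.3 ms-SD blip on an integer sample grid centered at t = 0
  tc <- exp(-(seq(-14L, 14L) * 1000 / fs)^2 / (2 * 0.15^2))
  for (f in footprints) {
    lagSamp <- round(f$lagMs / 1000 * fs)
    blip <- f$ampUv * matrix(tc, length(f$channels), length(tc), byrow = TRUE)
    for (c0 in round(trig * fs) + 1L + lagSamp) {
      idx <- (c0 - 14L):(c0 + 14L)
      mat[f$channels, idx] <- mat[f$channels, idx] + blip
    }
  }
  list(rec = rawRecording(mat, layout, samplingRate = fs), triggers = trig)
}

# A bank of varied noise-free template specifications.
templateBank <- function(nAxons, nSomas, layout) {
  n <- nChannels(layout)
  pcs <- round(seq(20, n - 20, length.out = nAxons + nSomas))
  specs <- list()
  for (i in seq_len(nAxons)) {
    specs[[paste0("ax", i)]] <- templateSpec(
      "axon", peakChannel = pcs[i],
      spreadChannels = 8L + (i %% 6L) * 2L,
      dfSpreadChannels = 12L + (i %% 6L) * 2L,
      reboundMs = 1.2 + 0.1 * (i %% 8L))
  }
  for (i in seq_len(nSomas)) {
    sc <- 0.6 + 0.1 * (i %% 8L)
    specs[[paste0("so", i)]] <- templateSpec(
      "soma", peakChannel = pcs[nAxons + i],
      negAmpUv = -54.9 * sc, posAmpUv = 24.6 * sc,
      spreadChannels = 4L + (i %% 8L))
  }
  specs
}

# Render one unit's recording and extract its MCW (regularly spaced
# spikes; spacing exceeds the MCW window so snippets never overlap).
noisyMcw <- function(spec, layout, nSpikes, noiseSdUv, seed, rateHz = 90) {
  st <- seq(0.05, by = 1 / rateHz, length.out = nSpikes)
  units <- sortedUnits(list(u = st), duration = max(st) + 0.05)
  rec <- renderRecording(units, list(u = spec), layout,
                         noiseSdUv = noiseSdUv, seed = seed)
  extractMcw(rec, st, seed = seed)
}

# All-pairs brute-force CCG oracle (independent of the binned path).
bruteCcg <- function(pre, post, binMs = 0.1, maxLagMs = 10) {
  d <- as.vector(outer(post, pre, "-")) * 1000
  edges <- seq(-maxLagMs, maxLagMs, by = binMs)
  vapply(seq_len(length(edges) - 1L),
         function(i) sum(d >= edges[i] & d < edges[i + 1L]), 0)
}

# Homogeneous Poisson train (no refractoriness), for calibration tests.
poissonTrain <- function(rateHz, durS) {
  n <- stats::rpois(1L, rateHz * durS)
  sort(stats::runif(n, 0, durS))
}
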