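test_that("CCG bins lag differences into half-open bins", {
  ccg <- computeCcg(1.000, 1.002)
  expect_equal(sum(ccg$counts), 1)
  expect_equal(ccg$lagsMs[ccg$counts == 1], 2.05)  # bin [2.0, 2.1)
  expect_warning(z <- computeCcg(numeric(0), c(1, 2)), "empty")
  expect_true(all(z$counts == 0))
  expect_error(computeCcg(1, 2, binMs = 0), "invalid-argument")
})

test_that("CCG matches the all-pairs brute force exactly and is antisymmetric", {
  set.seed(31)
  for (rep in 1:3) {
    a <- sort(runif(400, 0, 20))
    b <- sort(runif(500, 0, 20))
    fast <- computeCcg(a, b)$counts
    expect_identical(as.numeric(fast), as.numeric(bruteCcg(a, b)))
    # CCG(a,b)(tau) = CCG(b,a)(-tau)
    expect_identical(as.numeric(fast), rev(as.numeric(computeCcg(b, a)$counts)))
  }
})

test_that("independent Poisson pairs give the closed-form coincidence rate", {
  set.seed(32)
  a <- poissonTrain(10, 100)
  b <- poissonTrain(10, 100)
  counts <- computeCcg(a, b)$counts
  # E[count per bin] = rA * rB * T * binWidth = 10*10*100*1e-4 = 1.0
  expect_equal(mean(counts), 1.0, tolerance = 0.25)
})

test_that("jitter correction zeroes independent pairs on average", {
  devs <- sapply(1:20, function(s) {
    set.seed(1000 + s)
    a <- poissonTrain(10, 100)
    b <- poissonTrain(10, 100)
    cc <- jitterCorrect(a, b, seed = s)
    corr <- correctedCounts(cc)
    mean(corr) / (sd(corr) / sqrt(length(corr)))
  })
  expect_lt(abs(mean(devs)), 3)
  # raw = corrected + jitterMean holds exactly by construction
  set.seed(1)
  cc <- jitterCorrect(poissonTrain(5, 50), poissonTrain(5, 50), seed = 2)
  expect_equal(correctedCounts(cc) + cc@jitterMean, rawCounts(cc))
  expect_error(jitterCorrect(1, 2, jitterWindowMs = 0.05, seed = 1),
               "invalid-argument")
  empty <- jitterCorrect(c(1, 2), numeric(0), seed = 3)
  expect_true(all(correctedCounts(empty) == 0))
})

test_that("the corrected peak integrates to the transmitted-spike count", {
  conn <- data.frame(pre_id = "a", post_id = "b", prob = 0.1,
                     delay_ms = 2, jitter_sd_ms = 0.2)
  sim <- simulateTrains(c(a = 15, b = 10), 600, connections = conn, seed = 41)
  nEvoked <- sum(transmittedFlags(sim$truth, "a", "b"))
  cc <- jitterCorrect(spikeTimes(sim$units, "a"), spikeTimes(sim$units, "b"),
                      seed = 42)
  win <- lagsMs(cc) >= 1 & lagsMs(cc) <= 3
  # the surrogate mean re-absorbs W/J of the peak's own mass
  got <- sum(correctedCounts(cc)[win]) / (1 - 2 / 10)
  expect_lt(abs(got - nEvoked), 3 * sqrt(nEvoked))
})

test_that("detection requires 4 consecutive bins above 3 SD in the 0.5-4 ms window", {
  lags <- seq(-9.95, 9.95, by = 0.1)
  noise <- rep_len(c(-1, 1), length(lags))  # baseline SD ~ 1
  flat <- correctedCcg(lags, noise, nPre = 1000L)
  expect_null(detectConnection(flat))

  peaked3 <- noise; peaked3[lags > 2 & lags < 2.35] <- 10
  expect_null(detectConnection(correctedCcg(lags, peaked3, nPre = 1000L)))

  peaked4 <- noise; peaked4[lags > 2 & lags < 2.45] <- 10
  conn <- detectConnection(correctedCcg(lags, peaked4, nPre = 1000L))
  expect_s3_class(conn, "connection")
  expect_equal(conn$peakLagMs, 2.05, tolerance = 0.11)
  expect_length(conn$sigBins, 4)

  # a peak outside the monosynaptic window is ignored
  late <- noise; late[lags > 5 & lags < 5.55] <- 10
  expect_null(detectConnection(correctedCcg(lags, late, nPre = 1000L)))

  degenerate <- correctedCcg(lags, rep(0, length(lags)))
  expect_error(detectConnection(degenerate), "degenerate")
})

test_that("planted connections are detected at the planted delay", {
  conn <- data.frame(pre_id = "a", post_id = "b", prob = 0.05,
                     delay_ms = 2, jitter_sd_ms = 0.2)
  sim <- simulateTrains(c(a = 15, b = 5), 1400, connections = conn, seed = 51)
  expect_gte(length(spikeTimes(sim$units, "a")), 20000)
  cc <- jitterCorrect(spikeTimes(sim$units, "a"), spikeTimes(sim$units, "b"),
                      seed = 52)
  det <- detectConnection(cc)
  expect_false(is.null(det))
  expect_equal(det$peakLagMs, 2, tolerance = 0.3)
})

test_that("efficacy clips at zero and is NA without presynaptic spikes", {
  lags <- seq(-9.95, 9.95, by = 0.1)
  noise <- rep_len(c(-1, 1), length(lags))
  fake <- structure(list(peakLagMs = 2.05, peakHeightSd = 1,
                         sigBins = which(lags > 2 & lags < 2.45)),
                    class = "connection")
  dipped <- noise; dipped[lags > 2 & lags < 2.45] <- -2
  expect_equal(connectionEfficacy(correctedCcg(lags, dipped, nPre = 1000L), fake), 0)
  expect_true(is.na(connectionEfficacy(correctedCcg(lags, noise, nPre = 0L), fake)))
})

test_that("slow co-modulation without a connection is not detected", {
  hits <- 0L
  nSeeds <- 40
  for (s in seq_len(nSeeds)) {
    set.seed(3000 + s)
    # common 1 Hz rate modulation, independent spiking given the rate
    thin <- function() {
      cand <- poissonTrain(40, 300)
      cand[runif(length(cand)) < 0.5 * (1 + 0.8 * sin(2 * pi * cand))]
    }
    cc <- jitterCorrect(thin(), thin(), seed = s)
    det <- tryCatch(detectConnection(cc), error = function(e) NULL)
    if (!is.null(det)) hits <- hits + 1L
  }
  expect_lte(hits / nSeeds, 0.05)
})

test_that("all pairs are tested directionally and the planted graph is recovered", {
  rates <- c(t1 = 15, t2 = 15, t3 = 15, t4 = 15, t5 = 15,
             v1 = 8, v2 = 8, v3 = 8, v4 = 8, v5 = 8, v6 = 8)
  conns <- data.frame(
    pre_id = rep(c("t1", "t2", "t3", "t4", "t5"), each = 3),
    post_id = c("v1", "v2", "v3", "v2", "v3", "v4", "v3", "v4", "v5",
                "v4", "v5", "v6", "v5", "v6", "v1"),
    prob = 0.1, delay_ms = 2, jitter_sd_ms = 0.2)
  sim <- simulateTrains(rates, 600, connections = conns, seed = 61,
                        labels = c(rep("TCA", 5), rep("V1N", 6)),
                        peakChannel = c(10L, 20L, 30L, 40L, 50L,
                                        12L, 22L, 32L, 42L, 52L, 62L))
  lay <- makeProbeLayout(96)
  map <- connectivityMap(sim$units, layout = lay, seed = 62)
  expect_equal(map$summary$nTested, 30L)
  got <- paste(map$connections$pre_id, map$connections$post_id)
  want <- paste(conns$pre_id, conns$post_id)
  expect_setequal(got, want)
  # every TCA diverges to 3 targets; convergence matches the planted graph
  expect_equal(unname(map$summary$divergence), rep(3, 5))
  expect_equal(unname(map$summary$convergence),
               as.numeric(table(factor(conns$post_id, paste0("v", 1:6)))))
  expect_equal(map$summary$detectionPct, 100 * 15 / 30)
  expect_true(all(map$connections$distance_um > 0))
})

test_that("distance between peak channels follows the probe geometry", {
  lay <- makeProbeLayout(96)
  expect_equal(pairDistance(lay, 7, 7), 0)
  expect_equal(pairDistance(lay, 1, 21), 200)   # 10 rows, same column
})
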