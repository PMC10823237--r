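#' Test all TCA-to-V1N pairs for monosynaptic connections
#'
#' Runs the jitter-corrected CCG detection over every labeled TCA
#' (presynaptic) x V1N (postsynaptic) pair -- positive lags only, the
#' thalamocortical direction -- and summarizes the result: tested and
#' detected counts, detection percentage, per-TCA divergence, per-V1N
#' convergence, median efficacy and median pair distance (when a layout
#' and peak channels are available).
#'
#' @param units a labeled [SortedUnits-class].
#' @param layout optional [ProbeLayout-class] for pair distances.
#' @param binMs,maxLagMs,jitterWindowMs,nSurrogates CCG parameters, see
#'   [jitterCorrect()].
#' @param sdThresh,minBins,windowMs detection parameters, see
#'   [detectConnection()].
#' @param seed integer master seed; each pair gets a derived sub-seed so
#'   results do not depend on pair order.
#' @return list with `connections` (data.frame: `pre_id`, `post_id`,
#'   `peak_lag_ms`, `peak_height_sd`, `efficacy`, `distance_um`) and
#'   `summary` (list: `nTca`, `nV1n`, `nTested`, `nDetected`,
#'   `detectionPct`, `divergence`, `convergence`, `medianEfficacy`,
#'   `medianDistanceUm`).
#' @export
connectivityMap <- function(units, layout = NULL, binMs = 0.1, maxLagMs = 10,
                            jitterWindowMs = 10, nSurrogates = 50,
                            sdThresh = 3, minBins = 4L, windowMs = c(0.5, 4),
                            seed = 1) {
  tab <- unitTable(units)
  tcas <- tab$unit_id[tab$label == "TCA"]
  v1ns <- tab$unit_id[tab$label == "V1N"]
  empty <- data.frame(pre_id = character(), post_id = character(),
                      peak_lag_ms = numeric(), peak_height_sd = numeric(),
                      efficacy = numeric(), distance_um = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(tcas) || !length(v1ns)) {
    warning("no TCA or no V1N units: empty connectivity map")
    return(list(connections = empty,
                summary = connectionSummary(0L, 0L,
                  divergence = stats::setNames(numeric(0), character(0)),
                  convergence = stats::setNames(numeric(0), character(0)))))
  }

  rows <- list()
  k <- 0L
  for (pre in tcas) {
    preT <- spikeTimes(units, pre)
    for (post in v1ns) {
      k <- k + 1L
      ccg <- jitterCorrect(preT, spikeTimes(units, post), binMs = binMs,
                           maxLagMs = maxLagMs, jitterWindowMs = jitterWindowMs,
                           nSurrogates = nSurrogates,
                           seed = deriveSeed(seed, paste0(pre, "|", post)))
      conn <- tryCatch(detectConnection(ccg, sdThresh = sdThresh,
                                        minBins = minBins, windowMs = windowMs),
                       error = function(e) NULL)
      if (is.null(conn)) next
      dist <- NA_real_
      if (!is.null(layout)) {
        pcs <- tab$peak_channel[match(c(pre, post), tab$unit_id)]
        if (!anyNA(pcs)) dist <- pairDistance(layout, pcs[1], pcs[2])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pre_id = pre, post_id = post,
        peak_lag_ms = conn$peakLagMs, peak_height_sd = conn$peakHeightSd,
        efficacy = connectionEfficacy(ccg, conn), distance_um = dist,
        stringsAsFactors = FALSE)
    }
  }
  connections <- if (length(rows)) do.call(rbind, rows) else empty

  divergence <- vapply(tcas, function(u) sum(connections$pre_id == u), 1)
  convergence <- vapply(v1ns, function(u) sum(connections$post_id == u), 1)
  summary <- connectionSummary(
    nDetected = nrow(connections), nTested = k,
    divergence = divergence, convergence = convergence,
    medianEfficacy = stats::median(connections$efficacy),
    medianDistanceUm = stats::median(connections$distance_um))
  summary$nTca <- length(tcas)
  summary$nV1n <- length(v1ns)
  list(connections = connections, summary = summary)
}

#' Connection-count summary arithmetic
#'
#' The headline ratios of a connectivity screen: detection percentage
#' (100 x detected / tested) and, when a recording count is given, the
#' mean number of connections per recording.
#'
#' @param nDetected,nTested detected and tested pair counts.
#' @param nRecordings optional recording count.
#' @param divergence,convergence optional per-unit connection counts.
#' @param medianEfficacy,medianDistanceUm optional medians to carry.
#' @return list with `nDetected`, `nTested`, `detectionPct`,
#'   `meanPerRecording` (if `nRecordings` given) and the carried fields.
#' @examples
#' connectionSummary(23, 82588)$detectionPct          # 0.0278...
#' connectionSummary(153, NA, nRecordings = 2)$meanPerRecording  # 76.5
#' @export
connectionSummary <- function(nDetected, nTested, nRecordings = NULL,
                              divergence = NULL, convergence = NULL,
                              medianEfficacy = NA_real_,
                              medianDistanceUm = NA_real_) {
  out <- list(
    nDetected = nDetected, nTested = nTested,
    detectionPct = if (isTRUE(nTested > 0)) 100 * nDetected / nTested else NA_real_,
    divergence = divergence, convergence = convergence,
    medianEfficacy = medianEfficacy, medianDistanceUm = medianDistanceUm
  )
  if (!is.null(nRecordings)) out$meanPerRecording <- nDetected / nRecordings
  out
}

#' Derive a deterministic sub-seed from a master seed and a name
#'
#' Hashes the name into the master seed so every stage or pair of a run
#' gets an independent, order-insensitive random substream; results stay
#' below 2^31.
#'
#' @param seed integer master seed.
#' @param name character tag of the substream.
#' @return integer seed
#' @export
deriveSeed <- function(seed, name) {
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 1073741789
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483629 + 1)
}
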