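#' Simulate connected spike trains with ground truth
#'
#' Each unit fires as a homogeneous Poisson process thinned by an
#' absolute refractory period.  For each connection, every presynaptic
#' spike independently triggers (with probability `prob`) one extra
#' postsynaptic spike at `delay_ms + Normal(0, jitter_sd_ms)`; evoked
#' spikes bypass the refractoriness check, so the expected spike
#' transmission efficacy equals `prob` exactly.  Which presynaptic spikes
#' transmitted is recorded per connection in the returned
#' [GroundTruth-class], making efficacy and detection exactly checkable.
#'
#' @param ratesHz named numeric vector of baseline rates (names = unit ids).
#' @param durationS recording duration, seconds.
#' @param refractoryMs absolute refractory period, ms (0 disables).
#' @param connections `NULL` or data.frame with columns `pre_id`,
#'   `post_id`, `prob` (in (0,1\]), `delay_ms` (> 0), `jitter_sd_ms`.
#' @param seed integer seed; output is deterministic given the seed.
#' @param labels character vector (recycled over units) of unit labels.
#' @param peakChannel integer vector (recycled), peak channel per unit.
#' @return list with elements `units` (a [SortedUnits-class]) and
#'   `truth` (a [GroundTruth-class]).
#' @examples
#' sim <- simulateTrains(c(tca1 = 10, v1n1 = 5), 60,
#'   connections = data.frame(pre_id = "tca1", post_id = "v1n1",
#'     prob = 0.1, delay_ms = 2, jitter_sd_ms = 0.2), seed = 1)
#' mean(transmittedFlags(sim$truth, "tca1", "v1n1"))  # ~0.1
#' @export
simulateTrains <- function(ratesHz, durationS, refractoryMs = 2,
                           connections = NULL, seed,
                           labels = "unclassified", peakChannel = NA_integer_) {
  if (missing(seed)) stop("invalid-argument: seed is required")
  if (any(ratesHz < 0)) stop("invalid-argument: rates must be >= 0")
  if (refractoryMs < 0) stop("invalid-argument: refractoryMs must be >= 0")
  if (is.null(names(ratesHz)))
    names(ratesHz) <- paste0("u", seq_along(ratesHz))
  if (!is.null(connections) && nrow(connections)) {
    need <- c("pre_id", "post_id", "prob", "delay_ms", "jitter_sd_ms")
    if (!all(need %in% names(connections)))
      stop("invalid-argument: connections needs columns ", paste(need, collapse = ", "))
    if (any(connections$delay_ms <= 0))
      stop("invalid-argument: connection delay must be > 0")
    if (any(connections$prob <= 0 | connections$prob > 1))
      stop("invalid-argument: transmission prob must be in (0, 1]")
    bad <- setdiff(c(connections$pre_id, connections$post_id), names(ratesHz))
    if (length(bad)) stop("invalid-argument: unknown unit in connections: ",
                          paste(bad, collapse = ", "))
  }

  set.seed(as.integer(seed))
  refS <- refractoryMs / 1000
  base <- lapply(names(ratesHz), function(id) {
    r <- ratesHz[[id]]
    if (r <= 0) return(numeric(0))
    n <- stats::rpois(1L, r * durationS)
    st <- sort(stats::runif(n, 0, durationS))
    if (refS > 0 && length(st) > 1L) st <- .thinRefractory(st, refS)
    st
  })
  names(base) <- names(ratesHz)

  spikes <- base
  transmitted <- list()
  connDf <- data.frame(pre_id = character(), post_id = character(),
                       prob = numeric(), delay_ms = numeric(),
                       jitter_sd_ms = numeric(), stringsAsFactors = FALSE)
  if (!is.null(connections) && nrow(connections)) {
    connDf <- as.data.frame(connections)[, c("pre_id", "post_id", "prob",
                                             "delay_ms", "jitter_sd_ms")]
    for (k in seq_len(nrow(connDf))) {
      pre <- as.character(connDf$pre_id[k])
      post <- as.character(connDf$post_id[k])
      preT <- base[[pre]]
      flags <- stats::runif(length(preT)) < connDf$prob[k]
      evoked <- preT[flags] + connDf$delay_ms[k] / 1000 +
        stats::rnorm(sum(flags), 0, connDf$jitter_sd_ms[k] / 1000)
      keep <- evoked >= 0 & evoked < durationS
      # flags track the spikes whose evoked partner landed inside the recording
      flags[flags][!keep] <- FALSE
      evoked <- evoked[keep]
      # an evoked spike resets the postsynaptic neuron: baseline spikes
      # within the refractory period of an evoked spike are suppressed
      # (evoked spikes themselves are never suppressed, so efficacy = p)
      if (refS > 0 && length(evoked)) {
        cur <- spikes[[post]]
        ev <- sort(evoked)
        idx <- findInterval(cur, ev)
        dL <- ifelse(idx >= 1L, cur - ev[pmax(idx, 1L)], Inf)
        dR <- ifelse(idx < length(ev), ev[pmin(idx + 1L, length(ev))] - cur, Inf)
        spikes[[post]] <- cur[pmin(dL, dR) >= refS]
      }
      spikes[[post]] <- sort(c(spikes[[post]], evoked))
      transmitted[[paste0(pre, "->", post)]] <- flags
    }
  }

  units <- sortedUnits(spikes, duration = durationS,
                       peakChannel = peakChannel, label = labels)
  truth <- new("GroundTruth", connections = connDf, templates = list(),
               transmitted = transmitted)
  list(units = units, truth = truth)
}

# drop spikes closer than refS to the last kept spike
.thinRefractory <- function(st, refS) {
  keep <- logical(length(st))
  last <- -Inf
  for (i in seq_along(st)) {
    if (st[i] - last >= refS) {
      keep[i] <- TRUE
      last <- st[i]
    }
  }
  st[keep]
}

#' @rdname trueConnections
setMethod("trueConnections", "GroundTruth", function(x) x@connections)

#' @rdname transmittedFlags
setMethod("transmittedFlags", "GroundTruth", function(x, pre, post) {
  key <- paste0(pre, "->", post)
  if (!key %in% names(x@transmitted)) stop("no such connection: ", key)
  x@transmitted[[key]]
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d connections, %d templates\n",
    nrow(object@connections), length(object@templates)))
})
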