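#' Simulate sparse-noise visual responses
#'
#' Emulates a sparse-noise mapping session: one target pixel is flashed
#' per frame (default 100 ms), every grid position is shown `nRepeats`
#' times in seeded random order, and the unit fires as a piecewise
#' homogeneous Poisson process at `baselineHz + gainMap[pixel]` during
#' each frame.  The returned stimulus log has the tab-separated layout
#' consumed by [computeRF()].
#'
#' @param gainMap numeric matrix (rows x cols), evoked rate gain in Hz
#'   per pixel; all entries must be >= 0.
#' @param baselineHz baseline rate in Hz.
#' @param frameMs frame duration in ms.
#' @param nRepeats presentations per pixel.
#' @param seed integer seed.
#' @param polarity stimulus polarity recorded in the log (+1 light,
#'   -1 dark).
#' @return list with `stimLog` (data.frame: `frame_onset_s`, `pixel_row`,
#'   `pixel_col`, `polarity`), `spikeTimes` (seconds) and `durationS`.
#' @export
simulateVisualResponses <- function(gainMap, baselineHz = 2, frameMs = 100,
                                    nRepeats = 20, seed, polarity = 1L) {
  if (missing(seed)) stop("invalid-argument: seed is required")
  if (any(gainMap < 0)) stop("invalid-argument: gains must be >= 0")
  set.seed(as.integer(seed))
  nr <- nrow(gainMap); nc <- ncol(gainMap)
  pix <- expand.grid(pixel_row = seq_len(nr), pixel_col = seq_len(nc))
  order <- unlist(lapply(seq_len(nRepeats),
                         function(i) sample.int(nrow(pix))), use.names = FALSE)
  frames <- pix[order, ]
  frameS <- frameMs / 1000
  frames$frame_onset_s <- (seq_len(nrow(frames)) - 1L) * frameS
  frames$polarity <- polarity

  rates <- baselineHz + gainMap[cbind(frames$pixel_row, frames$pixel_col)]
  counts <- stats::rpois(nrow(frames), rates * frameS)
  spikes <- sort(rep(frames$frame_onset_s, counts) +
                   stats::runif(sum(counts), 0, frameS))
  list(
    stimLog = frames[, c("frame_onset_s", "pixel_row", "pixel_col", "polarity")],
    spikeTimes = spikes,
    durationS = nrow(frames) * frameS
  )
}

#' Simulate per-trial spike counts with a target Fano factor
#'
#' Repeated identical 1-s trials with controllable trial-to-trial
#' variability: Poisson for Fano 1, binomial thinning of a regular train
#' for sub-Poisson (Fano = 1 - p), and a rate-mixed (negative binomial)
#' process for super-Poisson counts (Fano = 1 + mean/size).
#'
#' @param nTrials number of trials (>= 2).
#' @param meanCount expected spikes per trial.
#' @param fano target Fano factor (>= 0).
#' @param seed integer seed.
#' @return integer vector of length `nTrials`
#' @seealso [fanoFactor()]
#' @export
simulateTrialCounts <- function(nTrials, meanCount, fano = 1, seed) {
  if (missing(seed)) stop("invalid-argument: seed is required")
  if (nTrials < 2) stop("invalid-argument: need >= 2 trials")
  if (fano < 0) stop("invalid-argument: fano must be >= 0")
  set.seed(as.integer(seed))
  if (fano == 0) {
    rep(as.integer(round(meanCount)), nTrials)
  } else if (fano < 1) {
    n <- max(1L, as.integer(round(meanCount / (1 - fano))))
    stats::rbinom(nTrials, n, meanCount / n)
  } else if (fano == 1) {
    stats::rpois(nTrials, meanCount)
  } else {
    stats::rnbinom(nTrials, size = meanCount / (fano - 1), mu = meanCount)
  }
}
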