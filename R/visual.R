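#' Receptive field from a sparse-noise stimulus log
#'
#' For every frame, spikes inside the frame window (optionally shifted
#' by a response latency) are counted and accumulated on the frame's
#' pixel; summing over repeats gives the evoked-response map.  The map
#' is then cubic-interpolated to twice the resolution along both axes,
#' and a signal-to-noise ratio is computed as 1/SD of the
#' peak-normalized map; maps with SNR above `snrThresh` (default 15)
#' pass the placement filter.
#'
#' @param spikeTimesS spike times, seconds.
#' @param stimLog data.frame with `frame_onset_s`, `pixel_row`,
#'   `pixel_col` (as produced by [simulateVisualResponses()]).
#' @param gridShape c(rows, cols) of the stimulus grid (default 36 x 22).
#' @param frameMs frame duration, ms.
#' @param latencyMs response-window shift, ms (default 0: the full frame).
#' @param snrThresh SNR pass threshold.
#' @return list of class `"receptiveField"`: `grid` (rows x cols summed
#'   evoked counts), `interpGrid` (2x cubic interpolation), `snr`,
#'   `passes`, `peak` (c(row, col) of the map maximum).
#' @export
computeRf <- function(spikeTimesS, stimLog, gridShape = c(36, 22),
                      frameMs = 100, latencyMs = 0, snrThresh = 15) {
  if (!nrow(stimLog)) stop("empty-input: stimulus log has no frames")
  grid <- matrix(0, gridShape[1], gridShape[2])
  frameS <- frameMs / 1000
  on <- stimLog$frame_onset_s + latencyMs / 1000
  # spikes per frame window [on, on + frame)
  n0 <- findInterval(on, spikeTimesS, left.open = TRUE)
  n1 <- findInterval(on + frameS, spikeTimesS, left.open = TRUE)
  counts <- n1 - n0
  for (i in seq_len(nrow(stimLog))) {
    grid[stimLog$pixel_row[i], stimLog$pixel_col[i]] <-
      grid[stimLog$pixel_row[i], stimLog$pixel_col[i]] + counts[i]
  }
  interp <- .interp2x(grid)
  mx <- max(grid)
  snr <- if (mx > 0) 1 / stats::sd(grid / mx) else 0
  pk <- which(grid == mx, arr.ind = TRUE)[1, ]
  structure(list(
    grid = grid, interpGrid = interp, snr = snr,
    passes = snr > snrThresh, peak = unname(pk)
  ), class = "receptiveField")
}

# separable cubic-spline interpolation to double resolution
.interp2x <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  xr <- seq(1, nr, length.out = 2L * nr)
  xc <- seq(1, nc, length.out = 2L * nc)
  half <- t(apply(m, 1L, function(v) stats::spline(seq_len(nc), v, xout = xc)$y))
  apply(half, 2L, function(v) stats::spline(seq_len(nr), v, xout = xr)$y)
}

#' Fano factor of trial spike counts
#'
#' Trial-to-trial variance (unbiased, n-1 denominator) divided by the
#' mean count over repeated identical trials.  1 for a Poisson process,
#' 0 for a deterministic train; thalamic units run sub-Poisson and
#' cortical units super-Poisson under repeated visual stimulation.
#'
#' @param counts integer vector of spikes per trial (>= 2 trials).
#' @return variance/mean, or `NA` when the mean count is 0
#' @export
fanoFactor <- function(counts) {
  if (length(counts) < 2L) stop("invalid-argument: need >= 2 trials")
  m <- mean(counts)
  if (m == 0) return(NA_real_)
  stats::var(counts) / m
}
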