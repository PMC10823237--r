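#' Build a deterministic probe layout
#'
#' Generates the channel geometry of a high-density shank.  The
#' `"two-column-stagger"` preset places two channels on every 20 um row
#' with alternating horizontal stagger (the classic 384-channel
#' checkerboard); `"four-column"` places four channels per row.  ADC
#' groups take 12 consecutive channels each; within a group the sampling
#' rank is the channel's position (0-based), giving the 2.78 us per-rank
#' acquisition stagger corrected by [correctAdcOffsets()].
#'
#' @param nChannels even integer >= 2 (divisible by 4 for `"four-column"`).
#' @param preset `"two-column-stagger"` or `"four-column"`.
#' @param verticalPitch row pitch in um (default 20).
#' @param adcGroupSize channels per ADC group (default 12).
#' @return a [ProbeLayout-class]
#' @examples
#' lay <- makeProbeLayout(384)
#' diff(range(channelPositions(lay)[, "y"]))  # 3820 um vertical span
#' @export
makeProbeLayout <- function(nChannels, preset = c("two-column-stagger", "four-column"),
                            verticalPitch = 20, adcGroupSize = 12L) {
  preset <- match.arg(preset)
  if (length(nChannels) != 1L || is.na(nChannels) || nChannels < 2 || nChannels %% 2 != 0)
    stop("invalid-argument: nChannels must be an even integer >= 2")
  nChannels <- as.integer(nChannels)
  if (preset == "four-column" && nChannels %% 4 != 0)
    stop("invalid-argument: four-column preset needs nChannels divisible by 4")

  i <- seq_len(nChannels) - 1L
  if (preset == "two-column-stagger") {
    row <- i %/% 2L
    col <- i %% 2L
    # odd rows shifted by half the horizontal spacing (checkerboard)
    x <- col * 32 + (row %% 2L) * 16
    nCol <- 2L
  } else {
    row <- i %/% 4L
    col <- i %% 4L
    x <- col * 16
    nCol <- 4L
  }
  y <- row * verticalPitch
  pos <- cbind(x = as.numeric(x), y = as.numeric(y))
  new("ProbeLayout",
    positions = pos,
    adcGroup = as.integer(i %/% adcGroupSize + 1L),
    adcRank = as.integer(i %% adcGroupSize),
    verticalPitch = as.numeric(verticalPitch),
    nColumns = nCol,
    preset = preset
  )
}

#' @describeIn makeProbeLayout Euclidean distance (um) between the
#'   positions of two channels (1-based indices); symmetric and zero on
#'   the diagonal.
#' @param layout a [ProbeLayout-class]
#' @param chA,chB channel indices (1-based)
#' @export
pairDistance <- function(layout, chA, chB) {
  n <- nChannels(layout)
  if (any(c(chA, chB) < 1L) || any(c(chA, chB) > n))
    stop("invalid-argument: channel index out of range")
  p <- layout@positions
  sqrt(rowSums((p[chA, , drop = FALSE] - p[chB, , drop = FALSE])^2))
}

#' @rdname nChannels
setMethod("nChannels", "ProbeLayout", function(x) nrow(x@positions))

#' @rdname nChannels
setMethod("nChannels", "RawRecording", function(x) nrow(x@samples))

#' @rdname channelPositions
setMethod("channelPositions", "ProbeLayout", function(x) x@positions)

#' @rdname adcRank
setMethod("adcRank", "ProbeLayout", function(x) x@adcRank)

setMethod("show", "ProbeLayout", function(object) {
  cat(sprintf("ProbeLayout '%s': %d channels, %d columns, %g um pitch, %g um span\n",
    object@preset, nChannels(object), object@nColumns,
    object@verticalPitch, diff(range(object@positions[, "y"]))))
})
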