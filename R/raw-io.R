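#' Construct a RawRecording
#'
#' @param samples numeric matrix, channels x time, in uV.
#' @param layout a [ProbeLayout-class].
#' @param samplingRate Hz (default 30000).
#' @param gainUv uV per int16 count (default 0.195, typical AP-band gain).
#' @return a [RawRecording-class]
#' @export
rawRecording <- function(samples, layout, samplingRate = 30000, gainUv = 0.195) {
  new("RawRecording", samples = samples, layout = layout,
      samplingRate = samplingRate, gainUv = gainUv)
}

#' @rdname samplingRate
setMethod("samplingRate", "RawRecording", function(x) x@samplingRate)

#' @rdname durationS
setMethod("durationS", "RawRecording", function(x) ncol(x@samples) / x@samplingRate)

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording: %d channels x %d samples (%.3f s at %g Hz), gain %g uV/bit\n",
    nrow(object@samples), ncol(object@samples), durationS(object),
    object@samplingRate, object@gainUv))
})

#' Write / read a flat-binary recording with its meta file
#'
#' The binary is frame-interleaved little-endian int16 (all channels of
#' sample 1, then sample 2, ...), the de-facto flat-binary dialect of
#' high-density probes; `<path>.meta` is key=value text carrying channel
#' count, sample count, sampling rate, gain and the layout preset.
#' Samples are quantized to int16 counts (`round(uV / gain)`), so a
#' write/read roundtrip is bit-exact at 16-bit resolution.
#'
#' @param rec a [RawRecording-class]
#' @param path file stem; `<path>.bin` and `<path>.meta` are written.
#' @return `writeRawRecording` returns `path` invisibly;
#'   `readRawRecording` returns a [RawRecording-class].
#' @export
writeRawRecording <- function(rec, path) {
  stopifnot(is(rec, "RawRecording"))
  counts <- round(rec@samples / rec@gainUv)
  if (any(abs(counts) > 32767))
    stop("format-error: samples exceed int16 range at this gain")
  storage.mode(counts) <- "integer"
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  # channels x time written column-major == frame-interleaved
  writeBin(as.vector(counts), con, size = 2L, endian = "little")
  meta <- c(
    n_channels = nrow(rec@samples),
    n_samples = ncol(rec@samples),
    sampling_rate_hz = rec@samplingRate,
    gain_uv_per_bit = rec@gainUv,
    layout_preset = rec@layout@preset,
    vertical_pitch_um = rec@layout@verticalPitch
  )
  writeLines(paste(names(meta), meta, sep = "="), paste0(path, ".meta"))
  invisible(path)
}

#' @rdname writeRawRecording
#' @param layout optional [ProbeLayout-class]; by default rebuilt from the
#'   meta file's preset and channel count.
#' @export
readRawRecording <- function(path, layout = NULL) {
  metaPath <- paste0(path, ".meta")
  binPath <- paste0(path, ".bin")
  if (!file.exists(metaPath)) stop("format-error: missing meta file ", metaPath)
  if (!file.exists(binPath)) stop("format-error: missing binary file ", binPath)
  kv <- readLines(metaPath)
  kv <- kv[nzchar(kv)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- stats::setNames(as.list(vals), keys)
  nCh <- as.integer(meta$n_channels)
  nSamp <- as.integer(meta$n_samples)
  sz <- file.size(binPath)
  if (sz != nCh * nSamp * 2)
    stop(sprintf("format-error: binary holds %d bytes, meta declares %d channels x %d samples",
                 sz, nCh, nSamp))
  con <- file(binPath, "rb")
  on.exit(close(con))
  counts <- readBin(con, "integer", n = nCh * nSamp, size = 2L,
                    signed = TRUE, endian = "little")
  gain <- as.numeric(meta$gain_uv_per_bit)
  if (is.null(layout))
    layout <- makeProbeLayout(nCh, meta$layout_preset,
                              verticalPitch = as.numeric(meta$vertical_pitch_um))
  rawRecording(matrix(counts * gain, nrow = nCh), layout,
               samplingRate = as.numeric(meta$sampling_rate_hz), gainUv = gain)
}
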