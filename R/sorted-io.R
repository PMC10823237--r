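#' Construct a SortedUnits container
#'
#' @param spikes named list of numeric spike-time vectors (seconds);
#'   unsorted input is sorted per unit.
#' @param duration recording duration in seconds.
#' @param peakChannel integer vector (recycled), peak channel per unit.
#' @param label character vector (recycled): `"TCA"`, `"V1N"` or
#'   `"unclassified"`.
#' @return a [SortedUnits-class]
#' @export
sortedUnits <- function(spikes, duration, peakChannel = NA_integer_,
                        label = "unclassified") {
  if (is.null(names(spikes)) || any(!nzchar(names(spikes))))
    stop("invalid-argument: spike list must be named by unit id")
  spikes <- lapply(spikes, function(x) sort(as.numeric(x)))
  ids <- names(spikes)
  tab <- data.frame(
    unit_id = ids,
    peak_channel = as.integer(rep_len(peakChannel, length(ids))),
    label = rep_len(label, length(ids)),
    firing_rate_hz = vapply(spikes, length, 1L) / duration,
    stringsAsFactors = FALSE, row.names = NULL
  )
  new("SortedUnits", spikes = spikes, units = tab, duration = as.numeric(duration))
}

#' @rdname spikeTimes
setMethod("spikeTimes", "SortedUnits", function(x, unit) {
  unit <- as.character(unit)
  if (!unit %in% names(x@spikes)) stop("unknown unit id: ", unit)
  x@spikes[[unit]]
})

#' @rdname unitTable
setMethod("unitTable", "SortedUnits", function(x) x@units)

#' @rdname unitIds
setMethod("unitIds", "SortedUnits", function(x) x@units$unit_id)

#' @rdname durationS
setMethod("durationS", "SortedUnits", function(x) x@duration)

setMethod("show", "SortedUnits", function(object) {
  nsp <- sum(vapply(object@spikes, length, 1L))
  lab <- table(object@units$label)
  cat(sprintf("SortedUnits: %d units (%s), %d spikes, %.1f s\n",
    nrow(object@units),
    paste(sprintf("%s=%d", names(lab), lab), collapse = ", "),
    nsp, object@duration))
})

#' Set unit labels
#'
#' @param x a [SortedUnits-class]
#' @param labels character vector named by unit id, or unnamed of full length.
#' @return the modified [SortedUnits-class]
#' @export
setUnitLabels <- function(x, labels) {
  if (!is.null(names(labels))) {
    idx <- match(names(labels), x@units$unit_id)
    if (anyNA(idx)) stop("unknown unit id in labels")
    x@units$label[idx] <- unname(labels)
  } else {
    x@units$label <- rep_len(labels, nrow(x@units))
  }
  validObject(x)
  x
}

#' Write / read sorted-unit tables
#'
#' Two tab-separated files emulating spike-sorter output:
#' `<path>.spikes.tsv` (`spike_time_s`, `unit_id`) and `<path>.units.tsv`
#' (`unit_id`, `peak_channel`, `label`, `firing_rate_hz`, `duration_s`).
#' Reading sorts spike times per unit; non-finite spike times are a
#' format error.
#'
#' @param units a [SortedUnits-class]
#' @param path file stem.
#' @return `writeSortedUnits` returns `path` invisibly; `readSortedUnits`
#'   returns a [SortedUnits-class].
#' @export
writeSortedUnits <- function(units, path) {
  stopifnot(is(units, "SortedUnits"))
  long <- data.frame(
    spike_time_s = unlist(units@spikes, use.names = FALSE),
    unit_id = rep(names(units@spikes), vapply(units@spikes, length, 1L))
  )
  utils::write.table(long, paste0(path, ".spikes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tab <- units@units
  tab$duration_s <- units@duration
  utils::write.table(tab, paste0(path, ".units.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSortedUnits
#' @export
readSortedUnits <- function(path) {
  spikesPath <- paste0(path, ".spikes.tsv")
  unitsPath <- paste0(path, ".units.tsv")
  for (p in c(spikesPath, unitsPath))
    if (!file.exists(p)) stop("format-error: missing file ", p)
  long <- utils::read.delim(spikesPath, colClasses = c("numeric", "character"))
  if (!all(c("spike_time_s", "unit_id") %in% names(long)))
    stop("format-error: spike table needs columns spike_time_s, unit_id")
  if (nrow(long) && any(!is.finite(long$spike_time_s)))
    stop("format-error: non-finite spike times")
  tab <- utils::read.delim(unitsPath, colClasses = list(unit_id = "character"))
  spikes <- split(long$spike_time_s, factor(long$unit_id, levels = tab$unit_id))
  # units with zero spikes keep an empty slot
  spikes <- lapply(spikes, sort)
  out <- sortedUnits(spikes, duration = tab$duration_s[1],
                     peakChannel = tab$peak_channel, label = tab$label)
  out
}
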