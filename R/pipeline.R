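#' Run the full analysis pipeline
#'
#' Orchestrates the stages in order: input (simulation or files) ->
#' quality control -> MCW extraction -> classification -> connectivity
#' -> optional trial-variability summary, with per-stage seeds derived
#' from the master seed by name (see [deriveSeed()]) so adding a stage
#' never perturbs another.  Identical config + seed gives identical
#' output.
#'
#' @param config nested list.  Recognized blocks:
#'   \describe{
#'     \item{`seed`}{integer master seed (required).}
#'     \item{`simulate`}{`nChannels`, `preset`, `durationS`, `rates`
#'       (named), `labels`, `peakChannels`, `connections` (data.frame),
#'       `templates` (named list of [templateSpec()] argument lists),
#'       `noiseSdUv`, `render` (logical: render raw and classify from
#'       waveforms).}
#'     \item{`io`}{`sortedPath` (stem for [readSortedUnits()]) and
#'       optionally `rawPath` (stem for [readRawRecording()]).}
#'     \item{`qc`}{`refractoryMs`, `isiMaxPct`, `isolationMin`,
#'       `doubleCountMs`.}
#'     \item{`ccg`}{`binMs`, `maxLagMs`, `jitterWindowMs`, `nSurrogates`.}
#'     \item{`detect`}{`sdThresh`, `minBins`, `windowMs`.}
#'   }
#' @param outDir optional directory; when given, report tables are
#'   written there (also on stage failure, preserving partial output).
#' @return list of class `"pipelineReport"`: `qc`, `units`,
#'   `connections`, `summary`, `params`, `log`.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.null(config$seed)) stop("invalid-argument: config$seed is required")
  seed <- as.integer(config$seed)
  res <- list(params = config, log = character())
  note <- function(...) res$log <<- c(res$log, sprintf(...))
  fail <- function(stage, e) {
    if (!is.null(outDir)) try(writeReport(res, outDir), silent = TRUE)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }

  # --- input -----------------------------------------------------------
  rec <- NULL
  tryCatch({
    if (!is.null(config$simulate)) {
      sc <- config$simulate
      layout <- makeProbeLayout(sc$nChannels %||% 64L,
                                sc$preset %||% "two-column-stagger")
      sim <- simulateTrains(sc$rates, sc$durationS,
                            refractoryMs = sc$refractoryMs %||% 2,
                            connections = sc$connections,
                            seed = deriveSeed(seed, "simulate"),
                            labels = sc$labels %||% "unclassified",
                            peakChannel = sc$peakChannels %||% NA_integer_)
      units <- sim$units
      truth <- sim$truth
      if (isTRUE(sc$render)) {
        specs <- lapply(sc$templates, function(a) do.call(templateSpec, a))
        rec <- renderRecording(units, specs, layout,
                               noiseSdUv = sc$noiseSdUv %||% 10,
                               seed = deriveSeed(seed, "render"))
      }
      res$truth <- truth
      note("input: simulated %d units, %.0f s", length(unitIds(units)), sc$durationS)
    } else if (!is.null(config$io)) {
      units <- readSortedUnits(config$io$sortedPath)
      layout <- NULL
      if (!is.null(config$io$rawPath)) {
        rec <- readRawRecording(config$io$rawPath)
        layout <- rec@layout
      }
      note("input: read %d units from %s", length(unitIds(units)),
           config$io$sortedPath)
    } else stop("config needs a 'simulate' or 'io' block")
  }, error = function(e) fail("input", e))

  # --- quality control -------------------------------------------------
  tryCatch({
    qc <- config$qc %||% list()
    res$qc <- qualityReport(units,
                            refractoryMs = qc$refractoryMs %||% 1.5,
                            isiMaxPct = qc$isiMaxPct %||% 0.05,
                            isolationMin = qc$isolationMin %||% 10,
                            doubleCountMs = qc$doubleCountMs %||% 0.2)
    keep <- res$qc$unit_id[res$qc$passed]
    units <- .subsetUnits(units, keep)
    note("qc: %d of %d units passed", length(keep), nrow(res$qc))
  }, error = function(e) fail("qc", e))

  # --- MCW + classification -------------------------------------------
  tryCatch({
    if (!is.null(rec)) {
      tab <- unitTable(units)
      for (id in tab$unit_id) {
        mcw <- extractMcw(rec, spikeTimes(units, id),
                          seed = deriveSeed(seed, paste0("mcw|", id)))
        met <- waveformMetrics(mcw, rec@layout)
        units <- setUnitLabels(units, stats::setNames(classifyUnit(met), id))
      }
      note("classify: labels assigned from waveforms")
    } else {
      note("classify: using provided labels")
    }
    res$units <- unitTable(units)
  }, error = function(e) fail("classify", e))

  # --- connectivity ----------------------------------------------------
  tryCatch({
    cc <- config$ccg %||% list()
    dd <- config$detect %||% list()
    map <- connectivityMap(units, layout = layout,
                           binMs = cc$binMs %||% 0.1,
                           maxLagMs = cc$maxLagMs %||% 10,
                           jitterWindowMs = cc$jitterWindowMs %||% 10,
                           nSurrogates = cc$nSurrogates %||% 50,
                           sdThresh = dd$sdThresh %||% 3,
                           minBins = dd$minBins %||% 4L,
                           windowMs = dd$windowMs %||% c(0.5, 4),
                           seed = deriveSeed(seed, "connectivity"))
    res$connections <- map$connections
    res$summary <- map$summary
    note("connectivity: %d detected of %d tested (%.4f%%)",
         map$summary$nDetected, map$summary$nTested,
         map$summary$detectionPct %||% NA)
  }, error = function(e) fail("connectivity", e))

  class(res) <- "pipelineReport"
  if (!is.null(outDir)) writeReport(res, outDir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.subsetUnits <- function(units, ids) {
  new("SortedUnits",
      spikes = units@spikes[as.character(ids)],
      units = units@units[units@units$unit_id %in% ids, , drop = FALSE],
      duration = units@duration)
}

#' Write a pipeline report to tab-separated tables
#'
#' @param report a [runPipeline()] result (possibly partial).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  if (!is.null(report$qc)) wt(report$qc, "qc.tsv")
  if (!is.null(report$units)) wt(report$units, "units.tsv")
  if (!is.null(report$connections)) wt(report$connections, "connections.tsv")
  lines <- report$log
  if (!is.null(report$summary)) {
    s <- report$summary
    lines <- c(lines, "",
      sprintf("n_TCA\t%s", s$nTca %||% NA),
      sprintf("n_V1N\t%s", s$nV1n %||% NA),
      sprintf("n_tested\t%d", s$nTested),
      sprintf("n_detected\t%d", s$nDetected),
      sprintf("detection_pct\t%s", format(s$detectionPct)),
      sprintf("median_efficacy\t%s", format(s$medianEfficacy)),
      sprintf("median_distance_um\t%s", format(s$medianDistanceUm)),
      sprintf("mean_divergence\t%s", format(mean(s$divergence))),
      sprintf("mean_convergence\t%s", format(mean(s$convergence))))
  }
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
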