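#' Interspike-interval violation percentage
#'
#' Percentage of interspike intervals shorter than the refractory
#' period.  Units exceeding 0.05 percent are excluded by the standard
#' quality screen (see [qualityReport()]).
#'
#' @param spikeTimesS sorted spike times, seconds.
#' @param refractoryMs refractory period in ms (default 1.5).
#' @return percentage in \[0, 100\], or `NA` with fewer than 2 spikes
#' @export
isiViolationPct <- function(spikeTimesS, refractoryMs = 1.5) {
  if (length(spikeTimesS) < 2L) return(NA_real_)
  isi <- diff(spikeTimesS)
  100 * sum(isi < refractoryMs / 1000) / length(isi)
}

#' Remove double-counted spikes
#'
#' Within one unit, whenever two spikes fall closer than `windowMs` the
#' later one is dropped (a sorter artifact, not a physiological event).
#' Idempotent.
#'
#' @param spikeTimesS sorted spike times, seconds.
#' @param windowMs double-count window in ms (default 0.2).
#' @return cleaned spike-time vector
#' @export
removeDoubleCounted <- function(spikeTimesS, windowMs = 0.2) {
  if (length(spikeTimesS) < 2L) return(spikeTimesS)
  .thinRefractory(spikeTimesS, windowMs / 1000)
}

#' Isolation distance of a sorted unit
#'
#' Squared Mahalanobis distance -- under the unit's own feature
#' covariance -- of the n-th closest spike not belonging to the unit,
#' where n is the unit's spike count.  `NA` when fewer non-unit spikes
#' than unit spikes exist (the definition's boundary).  A singular
#' covariance is ridge-regularized (epsilon = 1e-6 x trace/dims) and
#' flagged with a warning.
#'
#' @param features numeric matrix, spikes x feature dimensions.
#' @param labels vector of unit labels per spike.
#' @param unitId the unit to score.
#' @return squared Mahalanobis distance, or `NA`
#' @export
isolationDistance <- function(features, labels, unitId) {
  inUnit <- labels == unitId
  nUnit <- sum(inUnit)
  nOther <- sum(!inUnit)
  if (nOther < nUnit) return(NA_real_)
  x <- features[inUnit, , drop = FALSE]
  mu <- colMeans(x)
  S <- stats::cov(x)
  if (!is.finite(determinant(S)$modulus) ||
      inherits(try(solve(S), silent = TRUE), "try-error")) {
    S <- S + diag(1e-6 * sum(diag(S)) / ncol(S), ncol(S))
    warning("singular feature covariance: ridge-regularized")
  }
  d2 <- stats::mahalanobis(features[!inUnit, , drop = FALSE], mu, S)
  sort(d2)[nUnit]
}

#' Unit quality report
#'
#' Applies the standard pre-analysis screens: double-counted spike
#' removal, interspike-interval violations (fail when strictly above
#' `isiMaxPct` = 0.05 percent) and isolation distance (fail when not
#' strictly above `isolationMin` = 10 a.u.; skipped when unavailable).
#' Boundary values (exactly 0.05 percent, exactly 10) pass and fail
#' respectively per the strict readings.
#'
#' @param units a [SortedUnits-class].
#' @param features optional spikes x dims feature matrix for isolation
#'   distance; row order must match `featureLabels`.
#' @param featureLabels unit label per feature row.
#' @param refractoryMs refractory period for the ISI screen (ms).
#' @param isiMaxPct maximum tolerated ISI violation percentage.
#' @param isolationMin minimum isolation distance.
#' @param doubleCountMs double-count window (ms).
#' @return data.frame with one row per unit: `unit_id`,
#'   `isi_violation_pct`, `isolation_distance`,
#'   `n_double_counted_removed`, `passed`.
#' @export
qualityReport <- function(units, features = NULL, featureLabels = NULL,
                          refractoryMs = 1.5, isiMaxPct = 0.05,
                          isolationMin = 10, doubleCountMs = 0.2) {
  ids <- unitIds(units)
  rows <- lapply(ids, function(id) {
    st <- spikeTimes(units, id)
    clean <- removeDoubleCounted(st, doubleCountMs)
    isiPct <- isiViolationPct(clean, refractoryMs)
    iso <- if (!is.null(features))
      isolationDistance(features, featureLabels, id) else NA_real_
    passed <- (is.na(isiPct) || isiPct <= isiMaxPct) &&
      (is.na(iso) || iso > isolationMin)
    data.frame(unit_id = id,
               isi_violation_pct = isiPct,
               isolation_distance = iso,
               n_double_counted_removed = length(st) - length(clean),
               passed = passed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
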