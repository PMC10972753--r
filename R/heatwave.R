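#' Construct a heatwave definition
#'
#' The benchmark rule flags two or more consecutive days with daily mean
#' temperature strictly above the cell's 95th-percentile threshold computed
#' over the baseline window.  `dynamic = TRUE` switches to an expanding
#' window: the threshold for target year y uses all daily means from the
#' baseline start through year y - 1, a simple representation of gradual
#' acclimatization under warming.
#'
#' @param percentile threshold percentile in (0, 100); default 95.
#' @param minRun minimum consecutive exceedance days; default 2.
#' @param baselineYears length-2 year window for the (static) threshold.
#' @param dynamic logical, expanding-window thresholds.
#' @return A \linkS4class{HeatwaveDefinition}.
#' @examples
#' heatwaveDefinition()                   # benchmark: 95th pct, 2-day runs
#' heatwaveSensitivityDefinition()        # 97.5th pct, 4-day runs
#' @export
heatwaveDefinition <- function(percentile = 95, minRun = 2,
                               baselineYears = c(1985, 2015),
                               dynamic = FALSE) {
  new("HeatwaveDefinition", percentile = percentile, minRun = minRun,
      baselineYears = baselineYears, dynamic = dynamic)
}

#' @rdname heatwaveDefinition
#' @export
heatwaveSensitivityDefinition <- function(baselineYears = c(1985, 2015)) {
  heatwaveDefinition(percentile = 97.5, minRun = 4,
                     baselineYears = baselineYears)
}

#' Per-cell temperature thresholds for heatwave detection
#'
#' `staticThreshold()` returns the empirical percentile (linear interpolation
#' between closest order statistics) of all baseline daily mean temperatures,
#' per cell.  `dynamicThreshold()` recomputes the percentile for each target
#' year over the expanding window from `baselineStart` through the year
#' before the target year, so a year's threshold never uses that year's data.
#'
#' @param x a \linkS4class{ClimateGrid}.
#' @param percentile percentile in (0, 100).
#' @param baselineYears length-2 inclusive year window.
#' @param baselineStart first year of the expanding window.
#' @param targetYears years to compute dynamic thresholds for; defaults to
#'   every grid year after `baselineStart`.
#' @return `staticThreshold()`: numeric vector, one threshold per cell (deg
#'   C).  `dynamicThreshold()`: numeric matrix (cells x target years).
#' @examples
#' clim <- generateClimate(climateGenConfig(nLat = 2, nLon = 2,
#'                                          startYear = 2000, endYear = 2005))
#' thr <- staticThreshold(clim, 95, c(2000, 2004))
#' @importFrom stats quantile
#' @export
staticThreshold <- function(x, percentile = 95, baselineYears = c(1985, 2015)) {
  stopifnot(percentile > 0, percentile < 100)
  keep <- colData(x)$year >= baselineYears[1] &
    colData(x)$year <= baselineYears[2]
  if (!any(keep)) stop("baseline window contains no days of this grid")
  apply(tmean(x)[, keep, drop = FALSE], 1L, quantile,
        probs = percentile / 100, type = 7, names = FALSE)
}

#' @rdname staticThreshold
#' @export
dynamicThreshold <- function(x, percentile = 95, baselineStart = 1985,
                             targetYears = NULL) {
  years <- colData(x)$year
  if (is.null(targetYears))
    targetYears <- sort(unique(years[years > baselineStart]))
  if (!length(targetYears) || min(targetYears) <= baselineStart)
    stop("target years must lie strictly after the history start")
  tm <- tmean(x)
  thr <- vapply(targetYears, function(y) {
    keep <- years >= baselineStart & years < y
    if (!any(keep)) stop("no history before target year ", y)
    apply(tm[, keep, drop = FALSE], 1L, quantile,
          probs = percentile / 100, type = 7, names = FALSE)
  }, numeric(nrow(tm)))
  thr <- matrix(thr, nrow = nrow(tm),
                dimnames = list(rownames(x), targetYears))
  thr
}

## Mark days belonging to maximal TRUE runs of length >= minRun, one cell.
.runFilter <- function(exceed, minRun) {
  r <- rle(exceed)
  keep <- r$values & r$lengths >= minRun
  rep(keep, r$lengths)
}

#' Detect heatwaves on a climate grid
#'
#' A day is a heatwave day iff it belongs to a maximal run of at least
#' `minRun` consecutive days with daily mean temperature strictly above the
#' cell's threshold (ties at the threshold are not exceedances).  Runs may
#' cross calendar-year boundaries; each day is attributed to its own year, so
#' annual heatwave-day counts (HWN) are additive.  Under a dynamic
#' definition, each day is compared against its own year's expanding-window
#' threshold and only years after the baseline start are scored.
#'
#' @param x a \linkS4class{ClimateGrid}.
#' @param definition a \linkS4class{HeatwaveDefinition}.
#' @param threshold optional override: a per-cell vector (static) or a
#'   cells x years matrix with year column names (dynamic); computed from
#'   `definition` when missing.
#' @param ... unused.
#' @return A \linkS4class{HeatwaveStats}.
#' @examples
#' clim <- generateClimate(climateGenConfig(nLat = 2, nLon = 2,
#'                                          startYear = 2000, endYear = 2009))
#' hw <- detectHeatwaves(clim, heatwaveDefinition(baselineYears = c(2000, 2007)))
#' hwn(hw)[, "2009"]
#' @export
setMethod("detectHeatwaves", "ClimateGrid",
          function(x, definition = heatwaveDefinition(), threshold = NULL, ...) {
  years <- colData(x)$year
  tm <- tmean(x)
  if (is.null(threshold)) {
    threshold <- if (definition@dynamic)
      dynamicThreshold(x, definition@percentile, definition@baselineYears[1])
    else staticThreshold(x, definition@percentile, definition@baselineYears)
  }
  if (is.matrix(threshold)) {
    thrYears <- as.integer(colnames(threshold))
    exceed <- matrix(FALSE, nrow(tm), ncol(tm))
    idx <- match(years, thrYears)
    scored <- !is.na(idx)
    exceed[, scored] <- tm[, scored, drop = FALSE] >
      threshold[, idx[scored], drop = FALSE]
  } else {
    exceed <- tm > threshold
  }
  mask <- t(apply(exceed, 1L, .runFilter, minRun = definition@minRun))
  yrs <- sort(unique(years))
  counts <- vapply(yrs, function(y)
    rowSums(mask[, years == y, drop = FALSE]), numeric(nrow(mask)))
  counts <- matrix(counts, nrow = nrow(mask),
                   dimnames = list(rownames(x), yrs))
  new("HeatwaveStats", mask = mask, hwn = counts,
      dayYear = as.integer(years), definition = definition)
})
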