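#' Simplified wet bulb globe temperature (WBGT)
#'
#' The simplified outdoor WBGT approximation from near-surface temperature
#' and relative humidity (solar radiation and wind terms are deliberately
#' dropped; they carry higher uncertainty and weaker effects at global
#' scale):
#' \deqn{WBGT = 0.567 T_a + 3.94 + 0.393 E}
#' with the vapour-pressure term
#' \deqn{E = \frac{RH}{100} \times 6.105 \times
#'       \exp\!\left(17.27 \frac{T_a}{237.7 + T_a}\right) \quad [hPa].}
#' Indoor exposure deducts the radiation contribution as a fixed offset:
#' \eqn{WBGT_{indoor} = WBGT_{outdoor} - 4}.
#'
#' @param Ta air temperature, deg C (vectorized; must stay above -237.7).
#' @param RH relative humidity, percent in [0, 100].
#' @param wbgt outdoor WBGT, deg C-WBGT.
#' @return `vapourTerm()` the vapour pressure E in hPa; `wbgtOutdoor()` and
#'   `wbgtIndoor()` WBGT in deg C-WBGT.
#' @examples
#' wbgtOutdoor(30, 50)   # about 29.26
#' wbgtIndoor(wbgtOutdoor(30, 50))
#' @export
vapourTerm <- function(Ta, RH) {
  if (any(!is.finite(Ta))) stop("Ta must be finite")
  if (any(Ta <= -237.7)) stop("Ta at or below -237.7 C is outside the formula's domain")
  if (any(RH < 0 | RH > 100)) stop("RH must lie in [0, 100]")
  RH / 100 * 6.105 * exp(17.27 * Ta / (237.7 + Ta))
}

#' @rdname vapourTerm
#' @export
wbgtOutdoor <- function(Ta, RH) {
  0.567 * Ta + 3.94 + 0.393 * vapourTerm(Ta, RH)
}

#' @rdname vapourTerm
#' @export
wbgtIndoor <- function(wbgt) {
  if (any(!is.finite(wbgt))) stop("wbgt must be finite")
  wbgt - 4
}

#' Daily WBGT triplet for the 4+4+4 workday approximation
#'
#' Computes outdoor WBGT from the daily mean and daily maximum temperatures
#' (each with the same daily relative humidity) and their midpoint, the
#' three values to which the 12-hour workday assigns 4 hours each.
#'
#' @param x a \linkS4class{ClimateGrid}.
#' @param ... unused.
#' @return A \linkS4class{WBGTGrid} with assays `wbgtMean`, `wbgtMax`,
#'   `wbgtHalf`, sharing the climate grid's row/column annotation.
#' @examples
#' clim <- generateClimate(climateGenConfig(nLat = 2, nLon = 2,
#'                                          startYear = 2000, endYear = 2000))
#' w <- computeWBGT(clim)
#' all(wbgtMax(w) >= wbgtMean(w))
#' @export
setMethod("computeWBGT", "ClimateGrid", function(x, ...) {
  wm <- wbgtOutdoor(tmean(x), relHumidity(x))
  wx <- wbgtOutdoor(tmax(x), relHumidity(x))
  se <- SummarizedExperiment(
    assays = list(wbgtMean = wm, wbgtMax = wx, wbgtHalf = (wm + wx) / 2),
    rowData = rowData(x), colData = colData(x),
    metadata = metadata(x))
  new("WBGTGrid", se)
})
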