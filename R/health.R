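#' Heatwave excess deaths
#'
#' Excess deaths attributable to heatwaves at a location are
#' \deqn{D_{hw} = POP \times MR \times (RR - 1) \times HWN,}
#' with POP the population, MR the baseline daily mortality rate (deaths per
#' person-day), RR the climate-zone relative risk of mortality on heatwave
#' days, and HWN the annual number of heatwave days.  The form is linear in
#' every argument, so cell-level deaths aggregate to regions by summation.
#'
#' @param pop population, persons (vectorized over cells).
#' @param mr baseline daily mortality rate, deaths per person-day.
#' @param rr relative risk on heatwave days (>= 1).
#' @param hwn heatwave days in the period.
#' @return Excess deaths, same shape as the broadcast inputs.
#' @examples
#' excessDeaths(1e6, 2e-5, 1.5, 10)  # 100 deaths
#' @export
excessDeaths <- function(pop, mr, rr, hwn) {
  if (any(pop < 0) || any(mr < 0) || any(hwn < 0))
    stop("pop, mr and hwn must be nonnegative")
  if (any(rr < 1)) stop("relative risks below 1 are not supported")
  pop * mr * (rr - 1) * hwn
}

#' Climate-zone assignment from warm-season climatology
#'
#' A reproducible stand-in for an externally supplied climate-zone map:
#' cells are ranked by their baseline warm-season mean temperature and cut
#' at quartiles into zones 1 (coolest) through 4 (hottest).  Supply a
#' per-cell zone vector directly wherever a study-specific map is available.
#'
#' @param x a \linkS4class{ClimateGrid} covering the baseline window.
#' @param baselineYears length-2 year window used for the climatology.
#' @return Integer vector of zone ids (1-4), one per cell.
#' @examples
#' clim <- generateClimate(climateGenConfig(nLat = 3, nLon = 4,
#'                                          startYear = 2000, endYear = 2002))
#' table(assignClimateZones(clim, c(2000, 2002)))
#' @importFrom stats quantile
#' @export
assignClimateZones <- function(x, baselineYears = c(1985, 2015)) {
  keep <- colData(x)$year >= baselineYears[1] &
    colData(x)$year <= baselineYears[2]
  if (!any(keep)) stop("baseline window contains no days of this grid")
  warm <- warmSeasonMask(rowData(x)$lat, colData(x)$doy)
  warm[, !keep] <- FALSE
  tm <- tmean(x)
  clim <- rowSums(tm * warm) / pmax(rowSums(warm), 1)
  cuts <- quantile(clim, c(0.25, 0.5, 0.75), names = FALSE)
  zone <- findInterval(clim, cuts) + 1L
  as.integer(zone)
}

#' Illustrative climate-zone relative risks
#'
#' Placeholder relative risks of mortality on heatwave days for the four
#' climate zones (cold to hot).  These are illustrative defaults for running
#' the pipeline end to end, not epidemiological estimates; studies must
#' supply their own zone-specific RR table (a named numeric vector or a CSV
#' read via [readRRTable()]).
#'
#' @return Named numeric vector mapping zone ids "1".."4" to RR values.
#' @export
illustrativeRRTable <- function() {
  c("1" = 1.030, "2" = 1.045, "3" = 1.060, "4" = 1.080)
}

#' Value of statistical life, transferred across income levels
#'
#' In `income_scaled` mode the anchor-economy VSL is transferred with a
#' constant income elasticity:
#' \eqn{VSL_r = VSL_{anchor} (y_r / y_{anchor})^\epsilon}.  In `equal_world`
#' mode every region is assigned the population-weighted mean of the
#' income-scaled VSLs (each region's income-based VSL times its population,
#' summed, divided by total population), the equal-valuation sensitivity.
#'
#' @param income per-capita income by region, USD/yr (> 0).
#' @param pop regional population (required for `equal_world`).
#' @param params a \linkS4class{VSLParams} from `vslParams()`.
#' @return Numeric vector of VSLs, one per region.
#' @examples
#' vslForRegion(c(65000, 32500), params = vslParams())
#' @export
vslForRegion <- function(income, pop = NULL, params = vslParams()) {
  validObject(params)
  if (any(income <= 0)) stop("incomes must be > 0")
  base <- params@anchorVSL *
    (income / params@anchorIncome)^params@incomeElasticity
  if (params@mode == "income_scaled") return(base)
  if (is.null(pop)) stop("equal_world mode needs regional populations")
  rep(sum(base * pop) / sum(pop), length(base))
}

#' @rdname vslForRegion
#' @param anchorVSL anchor-economy VSL, USD (2019 USD by convention).
#' @param anchorIncome anchor-economy per-capita income, USD/yr.
#' @param incomeElasticity transfer elasticity (default 1).
#' @param mode `"income_scaled"` or `"equal_world"`.
#' @export
vslParams <- function(anchorVSL = 11e6, anchorIncome = 65000,
                      incomeElasticity = 1.0, mode = "income_scaled") {
  new("VSLParams", anchorVSL = anchorVSL, anchorIncome = anchorIncome,
      incomeElasticity = incomeElasticity, mode = mode)
}

#' Monetize regional excess deaths
#'
#' Health loss per region is excess deaths times the regional VSL; the loss
#' is also expressed as a share of baseline regional GDP (annual value added
#' of the region's firms in the calibrated table).  An optional deflator
#' rescales between price bases (e.g. 2019 to 2020 USD).
#'
#' @param deaths named numeric, excess deaths per region.
#' @param vsl named numeric, VSL per region (same regions).
#' @param gdp named numeric, baseline annual GDP per region.
#' @param deflator multiplicative price-base adjustment (default 1).
#' @return data.frame with columns region, deaths, loss (USD) and
#'   lossShareGDP.
#' @examples
#' healthLossValue(c(R1 = 100), c(R1 = 1e6), c(R1 = 1e9))
#' @export
healthLossValue <- function(deaths, vsl, gdp, deflator = 1) {
  regions <- names(deaths)
  if (is.null(regions) || !setequal(regions, names(vsl)) ||
      !setequal(regions, names(gdp)))
    stop("deaths, vsl and gdp must be named by the same regions")
  vsl <- vsl[regions]; gdp <- gdp[regions]
  loss <- deaths * vsl * deflator
  data.frame(region = regions, deaths = as.numeric(deaths),
             loss = as.numeric(loss),
             lossShareGDP = as.numeric(loss / gdp),
             row.names = NULL)
}

#' Regional excess deaths from gridded inputs
#'
#' Convenience aggregation of [excessDeaths()] over a population grid: each
#' populated cell contributes POP x MR x (RR(zone) - 1) x HWN, summed within
#' regions.  Mortality is taken from the grid's region table (finest
#' available resolution; supply a per-cell `mr` to override).
#'
#' @param popGrid a \linkS4class{PopulationGrid}.
#' @param hw a \linkS4class{HeatwaveStats} on the same grid.
#' @param zones integer per-cell climate zones (1-4).
#' @param rrTable named numeric RR per zone id.
#' @param years which HWN years to sum (default: all scored years).
#' @param mr optional per-cell daily mortality override.
#' @return Named numeric vector of excess deaths per region.
#' @export
regionalExcessDeaths <- function(popGrid, hw, zones,
                                 rrTable = illustrativeRRTable(),
                                 years = NULL, mr = NULL) {
  counts <- hwn(hw)
  if (is.null(years)) years <- as.integer(colnames(counts))
  use <- as.character(years)
  if (!all(use %in% colnames(counts))) stop("requested years not scored")
  days <- rowSums(counts[, use, drop = FALSE])
  if (length(days) != length(popGrid@pop))
    stop("heatwave stats and population grid have different cell counts")
  if (is.null(mr)) {
    rt <- popGrid@regionTable
    mr <- rt$mortality[match(popGrid@region, rt$region)]
  }
  rr <- rrTable[as.character(zones)]
  if (any(is.na(rr))) stop("rrTable is missing a zone present in the map")
  d <- excessDeaths(popGrid@pop, mr, rr, days)
  tapply(d, popGrid@region, sum)[sort(unique(popGrid@region))]
}
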