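#' ClimateGenConfig: settings for the synthetic climate generator
#'
#' @slot nLat,nLon integer grid dimensions.
#' @slot latRange,lonRange numeric(2), cell-centre coordinate spans (degrees).
#' @slot startYear,endYear integer calendar years (no-leap calendar).
#' @slot baseTemp numeric, per-cell annual-mean temperature (deg C); scalar
#'   values are broadcast, and `NA` requests the built-in meridional profile
#'   28 - 0.35 |lat|.
#' @slot seasonalAmplitude numeric, half-range of the seasonal cycle (deg C),
#'   phased so the warm peak falls in July north of the equator and January
#'   south of it.
#' @slot diurnalRange numeric, fixed daily max-minus-mean spread is half this
#'   value (deg C).
#' @slot ar1Rho numeric in [0, 1), lag-1 autocorrelation of daily anomalies.
#' @slot noiseSD numeric >= 0, innovation standard deviation (deg C).
#' @slot warmingRate numeric, secular linear trend in deg C per decade.
#' @slot rhMean numeric, mean relative humidity (percent).
#' @slot rhTempCoupling numeric, percent RH per deg C of temperature anomaly
#'   (negative couples dry to hot).
#' @slot scenario character label ("custom" unless set by
#'   [generateScenario()]).
#' @slot seed integer RNG seed; generation is a pure function of the config.
#' @seealso [climateGenConfig()], [generateClimate()]
#' @export
setClass("ClimateGenConfig", representation(
  nLat = "numeric", nLon = "numeric", latRange = "numeric",
  lonRange = "numeric", startYear = "numeric", endYear = "numeric",
  baseTemp = "numeric", seasonalAmplitude = "numeric",
  diurnalRange = "numeric", ar1Rho = "numeric", noiseSD = "numeric",
  warmingRate = "numeric", rhMean = "numeric", rhTempCoupling = "numeric",
  scenario = "character", seed = "numeric"))

setValidity("ClimateGenConfig", function(object) {
  msg <- NULL
  num <- c(object@nLat, object@nLon, object@latRange, object@lonRange,
           object@startYear, object@endYear, object@seasonalAmplitude,
           object@diurnalRange, object@ar1Rho, object@noiseSD,
           object@warmingRate, object@rhMean, object@rhTempCoupling,
           object@seed)
  if (any(!is.finite(num)))
    return("all numeric settings must be finite")
  if (any(!is.finite(object@baseTemp)) && !all(is.na(object@baseTemp)))
    msg <- c(msg, "baseTemp must be finite (or NA for the built-in profile)")
  if (object@nLat < 1 || object@nLon < 1) msg <- c(msg, "grid must be nonempty")
  if (object@ar1Rho < 0 || object@ar1Rho >= 1)
    msg <- c(msg, "ar1Rho must lie in [0, 1)")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (object@endYear < object@startYear)
    msg <- c(msg, "endYear must be >= startYear")
  if (object@diurnalRange < 0) msg <- c(msg, "diurnalRange must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Configure the synthetic climate generator
#'
#' Builds a validated \linkS4class{ClimateGenConfig}.  The generator emulates
#' the statistical structure the downstream analysis assumes: a seasonal
#' temperature cycle with hemisphere-dependent phase, AR(1)-autocorrelated
#' daily anomalies, a linear secular warming trend, and relative humidity
#' co-varying with the temperature anomaly.
#'
#' @param nLat,nLon grid dimensions.
#' @param startYear,endYear simulated calendar years (inclusive).
#' @param baseTemp per-cell annual-mean temperature (deg C); scalar recycled;
#'   `NA` (default) uses 28 - 0.35 |lat|.
#' @param seasonalAmplitude seasonal half-range, deg C.
#' @param diurnalRange daily tmax exceeds tmean by half this value, deg C.
#' @param ar1Rho lag-1 autocorrelation of daily anomalies, in [0, 1).
#' @param noiseSD anomaly innovation SD, deg C.
#' @param warmingRate linear warming, deg C per decade.
#' @param rhMean,rhTempCoupling humidity mean (percent) and its coupling to
#'   the temperature anomaly (percent per deg C).
#' @param latRange,lonRange coordinate spans of the cell centres.
#' @param scenario free-text scenario label.
#' @param seed integer RNG seed.
#' @return A \linkS4class{ClimateGenConfig}.
#' @examples
#' cfg <- climateGenConfig(nLat = 2, nLon = 2, startYear = 2000,
#'                         endYear = 2001, seed = 1)
#' clim <- generateClimate(cfg)
#' dim(tmean(clim))  # 4 cells x 730 days
#' @export
climateGenConfig <- function(nLat = 6, nLon = 10,
                             startYear = 1995, endYear = 2014,
                             baseTemp = NA_real_,
                             seasonalAmplitude = 8, diurnalRange = 8,
                             ar1Rho = 0.7, noiseSD = 2,
                             warmingRate = 0, rhMean = 65,
                             rhTempCoupling = -1.5,
                             latRange = c(-55, 65), lonRange = c(0, 350),
                             scenario = "custom", seed = 1L) {
  new("ClimateGenConfig", nLat = nLat, nLon = nLon, latRange = latRange,
      lonRange = lonRange, startYear = startYear, endYear = endYear,
      baseTemp = baseTemp, seasonalAmplitude = seasonalAmplitude,
      diurnalRange = diurnalRange, ar1Rho = ar1Rho, noiseSD = noiseSD,
      warmingRate = warmingRate, rhMean = rhMean,
      rhTempCoupling = rhTempCoupling, scenario = scenario, seed = seed)
}

## Evaluate expr with a private RNG stream so generators are pure functions
## of (config, seed) and never disturb the caller's RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.gridCoords <- function(config) {
  lat <- seq(config@latRange[1], config@latRange[2], length.out = config@nLat)
  lon <- seq(config@lonRange[1], config@lonRange[2], length.out = config@nLon)
  g <- expand.grid(lon = lon, lat = lat)  # lon fastest, lat-major rows
  data.frame(lat = g$lat, lon = g$lon)
}

#' Generate a synthetic daily climate grid
#'
#' Daily mean temperature is base + seasonal cycle + linear warming trend +
#' AR(1) anomaly; daily maximum adds half the diurnal range; relative
#' humidity is the configured mean plus a linear coupling to the temperature
#' anomaly, clipped to [0, 100].  Identical configs (including seed) give
#' bit-identical grids.
#'
#' @param config a \linkS4class{ClimateGenConfig}.
#' @return A \linkS4class{ClimateGrid}.
#' @importFrom stats rnorm
#' @export
generateClimate <- function(config) {
  validObject(config)
  coords <- .gridCoords(config)
  nc <- nrow(coords)
  cal <- noleapCalendar(config@startYear, config@endYear)
  nd <- nrow(cal)

  base <- config@baseTemp
  if (all(is.na(base))) base <- 28 - 0.35 * abs(coords$lat)
  base <- rep_len(base, nc)

  ## hemisphere-dependent seasonal phase: warm peak mid-July (doy 197) in the
  ## north, mid-January (doy 15) in the south
  peak <- ifelse(coords$lat >= -1, 197, 15)
  season <- config@seasonalAmplitude *
    cos(2 * pi * outer(peak, cal$doy, "-") / 365)

  trendYears <- (cal$year - config@startYear) + (cal$doy - 1) / 365
  trend <- matrix(config@warmingRate / 10 * trendYears, nc, nd, byrow = TRUE)

  anom <- .withSeed(config@seed, {
    if (config@noiseSD == 0) matrix(0, nc, nd)
    else {
      innov <- matrix(rnorm(nc * nd, sd = config@noiseSD), nc, nd)
      rho <- config@ar1Rho
      if (rho > 0) {
        ## stationary start, then recursive AR(1) filtering per cell
        innov[, 1] <- rnorm(nc, sd = config@noiseSD / sqrt(1 - rho^2))
        t(apply(innov, 1L, function(e)
          stats::filter(e, rho, method = "recursive", init = 0)))
      } else innov
    }
  })

  tm <- base + season + trend + anom
  tx <- tm + config@diurnalRange / 2
  rh <- pmin(pmax(config@rhMean + config@rhTempCoupling * anom, 0), 100)

  cellNames <- sprintf("cell%04d", seq_len(nc))
  dimnames(tm) <- dimnames(tx) <- dimnames(rh) <- NULL
  se <- SummarizedExperiment(
    assays = list(tmean = tm, tmax = tx, rh = rh),
    rowData = DataFrame(lat = coords$lat, lon = coords$lon,
                        row.names = cellNames),
    colData = DataFrame(year = cal$year, doy = cal$doy),
    metadata = list(scenario = config@scenario, seed = config@seed))
  new("ClimateGrid", se)
}

#' Scenario registry: warming-rate presets
#'
#' Maps the neutral labels `low`, `mid`, `high` (stand-ins for
#' low/medium/high-emission development paths) to monotonically increasing
#' linear warming rates applied by the climate generator.
#'
#' @return Named numeric vector of warming rates, deg C per decade.
#' @export
scenarioRegistry <- function() {
  c(low = 0.15, mid = 0.35, high = 0.75)
}

#' Derive a scenario climate config from a base config
#'
#' @param label one of `"low"`, `"mid"`, `"high"`.
#' @param base a \linkS4class{ClimateGenConfig} supplying everything except
#'   the warming rate.
#' @return The base config with the scenario's warming rate and label.
#' @examples
#' base <- climateGenConfig(seed = 7)
#' generateScenario("high", base)@warmingRate
#' @export
generateScenario <- function(label, base = climateGenConfig()) {
  reg <- scenarioRegistry()
  if (!label %in% names(reg))
    stop("unknown scenario label '", label, "'; expected one of: ",
         paste(names(reg), collapse = ", "))
  base@warmingRate <- unname(reg[label])
  base@scenario <- label
  validObject(base)
  base
}
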