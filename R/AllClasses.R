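#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
NULL

#' ClimateGrid: daily near-surface climate on a lat/lon grid
#'
#' A \linkS4class{SummarizedExperiment} whose rows are grid cells and whose
#' columns are days of a 365-day (no-leap) calendar.  Assays \code{tmean},
#' \code{tmax} (daily mean / maximum temperature, degrees C) and \code{rh}
#' (relative humidity, percent) are required.  \code{rowData} carries
#' \code{lat}, \code{lon} (cell-centre degrees) and optionally \code{region};
#' \code{colData} carries \code{year} and \code{doy} (day of year, 1-365).
#'
#' @seealso [generateClimate()], [computeWBGT()]
#' @export
setClass("ClimateGrid", contains = "SummarizedExperiment")

setValidity("ClimateGrid", function(object) {
  msg <- NULL
  need <- c("tmean", "tmax", "rh")
  if (!all(need %in% assayNames(object)))
    msg <- c(msg, sprintf("assays must include %s", paste(need, collapse = ", ")))
  else {
    tm <- assay(object, "tmean"); tx <- assay(object, "tmax")
    rh <- assay(object, "rh")
    if (any(!is.finite(tm)) || any(!is.finite(tx)) || any(!is.finite(rh)))
      msg <- c(msg, "non-finite values in climate assays")
    else {
      if (any(tx < tm - 1e-9)) msg <- c(msg, "tmax must be >= tmean everywhere")
      if (any(rh < 0) || any(rh > 100)) msg <- c(msg, "rh must lie in [0, 100]")
    }
  }
  if (!all(c("lat", "lon") %in% colnames(rowData(object))))
    msg <- c(msg, "rowData must contain lat and lon")
  if (!all(c("year", "doy") %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain year and doy")
  if (is.null(msg)) TRUE else msg
})

#' WBGTGrid: daily wet bulb globe temperature triplet
#'
#' A \linkS4class{SummarizedExperiment} (cells x days) holding the outdoor
#' WBGT triplet used by the 4+4+4 workday approximation: assays
#' \code{wbgtMean} (from daily mean temperature), \code{wbgtMax} (from daily
#' maximum temperature) and \code{wbgtHalf} (their midpoint), all in degrees
#' C-WBGT.  Indoor values are derived on demand by subtracting the fixed
#' indoor offset, never stored.
#'
#' @seealso [computeWBGT()], [wbgtIndoor()], [dailyLoss()]
#' @export
setClass("WBGTGrid", contains = "SummarizedExperiment")

setValidity("WBGTGrid", function(object) {
  msg <- NULL
  need <- c("wbgtMean", "wbgtMax", "wbgtHalf")
  if (!all(need %in% assayNames(object)))
    msg <- c(msg, sprintf("assays must include %s", paste(need, collapse = ", ")))
  else {
    wm <- assay(object, "wbgtMean"); wx <- assay(object, "wbgtMax")
    wh <- assay(object, "wbgtHalf")
    if (any(wx < wm - 1e-9)) msg <- c(msg, "wbgtMax must be >= wbgtMean")
    if (max(abs(wh - (wm + wx) / 2)) > 1e-9)
      msg <- c(msg, "wbgtHalf must equal (wbgtMean + wbgtMax)/2")
  }
  if (is.null(msg)) TRUE else msg
})

#' HeatwaveDefinition: percentile/run-length heatwave rule
#'
#' The benchmark rule is two or more consecutive days with daily mean
#' temperature strictly above the cell's 95th-percentile baseline threshold;
#' \code{dynamic = TRUE} recomputes the threshold per target year over the
#' expanding window ending the year before.  \code{sens975} is the packaged
#' sensitivity preset (97.5th percentile, 4-day minimum run).
#'
#' @slot percentile numeric, threshold percentile in (0, 100).
#' @slot minRun integer, minimum run length in days (>= 1).
#' @slot baselineYears integer(2), first and last baseline year.
#' @slot dynamic logical, expanding-window threshold recomputation.
#' @export
setClass("HeatwaveDefinition", representation(
  percentile = "numeric", minRun = "numeric",
  baselineYears = "numeric", dynamic = "logical"))

setValidity("HeatwaveDefinition", function(object) {
  msg <- NULL
  if (object@percentile <= 0 || object@percentile >= 100)
    msg <- c(msg, "percentile must lie in (0, 100)")
  if (object@minRun < 1) msg <- c(msg, "minRun must be >= 1")
  if (length(object@baselineYears) != 2 ||
      object@baselineYears[2] < object@baselineYears[1])
    msg <- c(msg, "baselineYears must be an increasing year pair")
  if (is.null(msg)) TRUE else msg
})

#' HeatwaveStats: per-cell heatwave-day counts and event masks
#'
#' @slot mask logical matrix (cells x days); TRUE on heatwave days, i.e. days
#'   belonging to a maximal exceedance run of at least \code{minRun} days.
#' @slot hwn numeric matrix (cells x years) of heatwave-day counts (HWN);
#'   each day of a boundary-crossing run is attributed to its own calendar
#'   year, so annual HWN is additive.
#' @slot dayYear integer, calendar year of each mask column.
#' @slot definition the \linkS4class{HeatwaveDefinition} used.
#' @export
setClass("HeatwaveStats", representation(
  mask = "matrix", hwn = "matrix", dayYear = "integer",
  definition = "HeatwaveDefinition"))

setValidity("HeatwaveStats", function(object) {
  msg <- NULL
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (length(object@dayYear) != ncol(object@mask))
    msg <- c(msg, "dayYear length must match mask columns")
  yrs <- sort(unique(object@dayYear))
  if (!identical(as.integer(colnames(object@hwn)), as.integer(yrs)))
    msg <- c(msg, "hwn columns must cover the mask years")
  else {
    chk <- vapply(yrs, function(y)
      rowSums(object@mask[, object@dayYear == y, drop = FALSE]), numeric(nrow(object@mask)))
    if (!isTRUE(all.equal(unname(object@hwn), matrix(chk, nrow = nrow(object@mask)))))
      msg <- c(msg, "hwn must equal per-year column sums of mask")
  }
  if (is.null(msg)) TRUE else msg
})

#' PopulationGrid: gridded population with region metadata
#'
#' @slot pop numeric vector, persons per cell (sums exactly to the configured
#'   total after largest-remainder rounding).
#' @slot lat,lon numeric, cell-centre coordinates.
#' @slot region character, region label per cell.
#' @slot regionTable data.frame with one row per region: \code{region},
#'   \code{mortality} (baseline deaths per person-day), \code{income}
#'   (USD per capita-year).
#' @export
setClass("PopulationGrid", representation(
  pop = "numeric", lat = "numeric", lon = "numeric",
  region = "character", regionTable = "data.frame"))

setValidity("PopulationGrid", function(object) {
  msg <- NULL
  n <- length(object@pop)
  if (any(lengths(list(object@lat, object@lon, object@region)) != n))
    msg <- c(msg, "pop, lat, lon, region must have equal length")
  if (any(object@pop < 0)) msg <- c(msg, "populations must be >= 0")
  rt <- object@regionTable
  if (!all(c("region", "mortality", "income") %in% names(rt)))
    msg <- c(msg, "regionTable needs region, mortality, income columns")
  else {
    if (any(rt$mortality <= 0) || any(rt$mortality >= 1))
      msg <- c(msg, "mortality rates must lie in (0, 1)")
    if (!all(object@region %in% rt$region))
      msg <- c(msg, "every cell region must appear in regionTable")
  }
  if (is.null(msg)) TRUE else msg
})

#' MRIOTable: balanced multiregional input-output table
#'
#' Firms are region-sector pairs.  \code{Z[i, j]} is the annual monetary flow
#' from supplier firm i to client firm j; \code{F[i, h]} the flow to the
#' representative household of region h; \code{va} the value-added row and
#' \code{x} gross outputs.  Both accounting identities
#' \eqn{x_i = \sum_j Z_{ij} + \sum_h F_{ih}} (row balance) and
#' \eqn{x_i = \sum_p Z_{pi} + va_i} (column balance) must hold to a relative
#' residual below 1e-6.
#'
#' @slot Z numeric matrix (firm x firm) of intermediate flows.
#' @slot F numeric matrix (firm x household) of final demand.
#' @slot va numeric, value added per firm.
#' @slot x numeric, gross output per firm.
#' @slot region,sector character, firm labels.
#' @seealso [generateMRIO()], [calibrateNetwork()]
#' @export
setClass("MRIOTable", representation(
  Z = "matrix", F = "matrix", va = "numeric", x = "numeric",
  region = "character", sector = "character"))

#' @importFrom stats na.omit
.mrioResiduals <- function(Z, F, va, x) {
  sc <- pmax(x, max(x) * 1e-12)
  row <- abs(rowSums(Z) + rowSums(F) - x) / sc
  col <- abs(colSums(Z) + va - x) / sc
  max(row, col)
}

setValidity("MRIOTable", function(object) {
  msg <- NULL
  n <- length(object@x)
  if (nrow(object@Z) != n || ncol(object@Z) != n || nrow(object@F) != n ||
      length(object@va) != n || length(object@region) != n ||
      length(object@sector) != n)
    msg <- c(msg, "inconsistent dimensions")
  else {
    if (any(object@Z < 0) || any(object@F < 0))
      msg <- c(msg, "flows must be nonnegative")
    if (any(object@x <= 0)) msg <- c(msg, "gross outputs must be positive")
    if (.mrioResiduals(object@Z, object@F, object@va, object@x) > 1e-6)
      msg <- c(msg, "table is not balanced (relative residual > 1e-6)")
  }
  if (is.null(msg)) TRUE else msg
})

#' CalibratedNetwork: supply-chain network at its equilibrium benchmark
#'
#' Calibration divides annual MRIO flows by the number of simulation steps,
#' so one no-shock step reproduces the equilibrium exactly and the per-step
#' baseline value added times the horizon equals annual value added.
#' Product classes coincide with sectors; \code{a[p, i]} is firm i's input
#' requirement of product p per unit output, \code{b[i]} its value-added
#' coefficient, with \eqn{\sum_p a_i^p + b_i = 1}.
#'
#' @slot Zbar,Fbar per-step baseline flows (orders at equilibrium).
#' @slot a numeric matrix (product x firm) of input coefficients.
#' @slot b numeric, value-added coefficients.
#' @slot xbar numeric, per-step equilibrium outputs.
#' @slot vaBar numeric, per-step equilibrium value added.
#' @slot HD numeric matrix (product x household), baseline household demand.
#' @slot region,sector character, firm labels; \code{households} character.
#' @slot products character, product-class (sector) names; \code{sectorIndex}
#'   integer mapping each firm to its product row.
#' @slot stepsPerYear integer, number of steps the annual table was split into.
#' @export
setClass("CalibratedNetwork", representation(
  Zbar = "matrix", Fbar = "matrix", a = "matrix", b = "numeric",
  xbar = "numeric", vaBar = "numeric", HD = "matrix",
  region = "character", sector = "character", households = "character",
  products = "character", sectorIndex = "integer", stepsPerYear = "numeric"))

setValidity("CalibratedNetwork", function(object) {
  msg <- NULL
  if (any(abs(colSums(object@a) + object@b - 1) > 1e-8))
    msg <- c(msg, "input coefficients must satisfy sum_p a + b = 1 per firm")
  if (any(object@a < 0) || any(object@b < 0))
    msg <- c(msg, "coefficients must be nonnegative")
  if (is.null(msg)) TRUE else msg
})

#' SimConfig: adaptive input-output simulation settings
#'
#' @slot horizon integer, number of steps (default 365 daily steps = 1 year).
#' @slot nTarget numeric, target inventory cover in steps (default 15).
#' @slot overproduction numeric >= 1, spare-capacity factor applied to the
#'   capacity minimum (default 1 = none).
#' @slot substitutionExponent numeric >= 0, exponent on the relative-capacity
#'   weight used when clients re-allocate orders across suppliers (0 = fixed
#'   baseline shares, 1 = capacity-proportional reallocation).
#' @export
setClass("SimConfig", representation(
  horizon = "numeric", nTarget = "numeric", overproduction = "numeric",
  substitutionExponent = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- NULL
  if (object@horizon < 1) msg <- c(msg, "horizon must be >= 1")
  if (object@nTarget < 0) msg <- c(msg, "nTarget must be >= 0")
  if (object@overproduction < 1) msg <- c(msg, "overproduction must be >= 1")
  if (object@substitutionExponent < 0)
    msg <- c(msg, "substitutionExponent must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' ShockSeries: exogenous shocks driving the simulator
#'
#' @slot gammaL numeric matrix (steps x firms), share of labour capacity
#'   unavailable at each step, in [0, 1].
#' @slot gammaK numeric matrix (steps x firms), share of productive capital
#'   unavailable, in [0, 1].
#' @slot HD numeric array (product x household x steps) of exogenous
#'   household demand, or a 0-extent array to use the calibrated baseline.
#' @export
setClass("ShockSeries", representation(
  gammaL = "matrix", gammaK = "matrix", HD = "array"))

setValidity("ShockSeries", function(object) {
  msg <- NULL
  bad <- function(g) any(g < 0) || any(g > 1)
  if (bad(object@gammaL)) msg <- c(msg, "gammaL must lie in [0, 1]")
  if (bad(object@gammaK)) msg <- c(msg, "gammaK must lie in [0, 1]")
  if (!identical(dim(object@gammaL), dim(object@gammaK)))
    msg <- c(msg, "gammaL and gammaK must share dimensions")
  if (length(object@HD) && any(object@HD < 0))
    msg <- c(msg, "household demand must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' FootprintResult: decomposed value-added losses from a simulation
#'
#' Time-integrated value-added shortfalls per firm: the total economic
#' footprint \eqn{TEF_i = \bar{va}_i T - \sum_t va^a_i(t)}, the direct
#' footprint \eqn{DEF_i = \bar{va}_i T - \sum_t va^{max}_i(t)} attributable
#' to the firm's own capacity constraints, and the propagated footprint
#' \eqn{PEF_i = TEF_i - DEF_i} transmitted through the supply chain.
#'
#' @slot tef,def,pef numeric, per-firm footprints (monetary units).
#' @slot vaA,vaMax numeric matrices (steps x firms), actual and maximum
#'   per-step value added.
#' @slot vaBar numeric, per-step baseline value added per firm.
#' @slot region,sector character firm labels; \code{horizon} numeric.
#' @export
setClass("FootprintResult", representation(
  tef = "numeric", def = "numeric", pef = "numeric",
  vaA = "matrix", vaMax = "matrix", vaBar = "numeric",
  region = "character", sector = "character", horizon = "numeric"))

setValidity("FootprintResult", function(object) {
  msg <- NULL
  if (max(abs(object@tef - object@def - object@pef)) >
      1e-6 * max(1, max(abs(object@tef))))
    msg <- c(msg, "TEF must equal DEF + PEF")
  if (is.null(msg)) TRUE else msg
})

#' LabourAvailability: daily labour-capacity losses per region-sector
#'
#' The bridge from climate to economy: \code{gamma[t, i]} is the share of
#' firm i's labour unavailable on simulation day t (population-weighted mean
#' of the effective daily work-capacity loss over the firm's region, for its
#' sector's work-intensity class), zero outside the hemisphere-specific warm
#' season.
#'
#' @slot gamma numeric matrix (days x region-sector firms) in [0, 1].
#' @slot year,doy integer, calendar coordinates of each day (no-leap).
#' @slot region,sector character, firm labels for the columns.
#' @export
setClass("LabourAvailability", representation(
  gamma = "matrix", year = "integer", doy = "integer",
  region = "character", sector = "character"))

setValidity("LabourAvailability", function(object) {
  msg <- NULL
  if (any(object@gamma < 0) || any(object@gamma > 1))
    msg <- c(msg, "gamma must lie in [0, 1]")
  if (nrow(object@gamma) != length(object@year) ||
      length(object@year) != length(object@doy))
    msg <- c(msg, "calendar length must match gamma rows")
  if (ncol(object@gamma) != length(object@region) ||
      length(object@region) != length(object@sector))
    msg <- c(msg, "region/sector labels must match gamma columns")
  if (is.null(msg)) TRUE else msg
})

#' VSLParams: value-of-statistical-life monetization settings
#'
#' @slot anchorVSL numeric, VSL in the anchor (highest-income reference)
#'   economy, USD (default 11e6, 2019 USD).
#' @slot anchorIncome numeric, per-capita income of the anchor economy,
#'   USD per year (default 65000).
#' @slot incomeElasticity numeric >= 0, elasticity used to transfer the
#'   anchor VSL to other income levels (default 1).
#' @slot mode character, \code{"income_scaled"} (default) or
#'   \code{"equal_world"} (population-weighted mean VSL applied everywhere).
#' @export
setClass("VSLParams", representation(
  anchorVSL = "numeric", anchorIncome = "numeric",
  incomeElasticity = "numeric", mode = "character"))

setValidity("VSLParams", function(object) {
  msg <- NULL
  if (object@anchorVSL <= 0) msg <- c(msg, "anchorVSL must be > 0")
  if (object@anchorIncome <= 0) msg <- c(msg, "anchorIncome must be > 0")
  if (object@incomeElasticity < 0) msg <- c(msg, "incomeElasticity must be >= 0")
  if (!object@mode %in% c("income_scaled", "equal_world"))
    msg <- c(msg, "mode must be income_scaled or equal_world")
  if (is.null(msg)) TRUE else msg
})

#' WorkIntensity: exposure-response parameters for a work-intensity class
#'
#' ISO-style metabolic classes: 200 W (light, office/services), 300 W
#' (moderate, industry) and 400 W (heavy, construction/agriculture).
#' \code{prodMean}/\code{prodSD} parameterize the cumulative-normal loss
#' curve; \code{alpha1}/\code{alpha2} the logistic (Hothaps) workability
#' curve used for sensitivity analysis.  Shipped defaults are illustrative
#' placeholders and should be replaced with study-specific estimates.
#'
#' @slot level numeric, metabolic rate in W (200, 300 or 400).
#' @slot setting character, \code{"indoor"} or \code{"outdoor"}.
#' @slot prodMean,prodSD numeric, degrees C-WBGT (prodSD > 0).
#' @slot alpha1,alpha2 numeric > 0, Hothaps shape parameters.
#' @export
setClass("WorkIntensity", representation(
  level = "numeric", setting = "character",
  prodMean = "numeric", prodSD = "numeric",
  alpha1 = "numeric", alpha2 = "numeric"))

setValidity("WorkIntensity", function(object) {
  msg <- NULL
  if (!object@setting %in% c("indoor", "outdoor"))
    msg <- c(msg, "setting must be indoor or outdoor")
  if (object@prodSD <= 0) msg <- c(msg, "prodSD must be > 0")
  if (object@alpha1 <= 0 || object@alpha2 <= 0)
    msg <- c(msg, "alpha1 and alpha2 must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' ACModel: climate-income air-conditioning penetration model
#'
#' Penetration is the product of a climate-driven saturation level (a
#' saturating function of the indoor-WBGT climatology: hotter places top out
#' at higher penetration) and an income logistic in log income.  Only indoor
#' work protected by air conditioning escapes heat-induced capacity loss.
#'
#' @slot satMax numeric in [0, 1], asymptotic penetration in the hottest
#'   climates.
#' @slot climBase numeric, indoor-WBGT climatology (deg C-WBGT) below which
#'   there is no cooling demand.
#' @slot climScale numeric > 0, e-folding scale of the saturation curve.
#' @slot incomeMidpoint numeric, income (USD/yr) at which the logistic
#'   reaches half its asymptote.
#' @slot incomeSlope numeric > 0, logistic steepness in log-income units.
#' @export
setClass("ACModel", representation(
  satMax = "numeric", climBase = "numeric", climScale = "numeric",
  incomeMidpoint = "numeric", incomeSlope = "numeric"))

setValidity("ACModel", function(object) {
  msg <- NULL
  if (object@satMax < 0 || object@satMax > 1)
    msg <- c(msg, "satMax must lie in [0, 1]")
  if (object@climScale <= 0) msg <- c(msg, "climScale must be > 0")
  if (object@incomeMidpoint <= 0) msg <- c(msg, "incomeMidpoint must be > 0")
  if (object@incomeSlope <= 0) msg <- c(msg, "incomeSlope must be > 0")
  if (is.null(msg)) TRUE else msg
})
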