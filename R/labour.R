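#' Work-intensity classes and the sector map
#'
#' `workIntensity()` builds the exposure-response parameter set for one ISO
#' metabolic class; `defaultSectorIntensityMap()` maps the packaged sectors
#' to classes: services are light indoor work (200 W), industry moderate
#' indoor work (300 W), construction and agriculture heavy outdoor work
#' (400 W).  The numeric exposure-response defaults are illustrative
#' placeholders to be replaced by study-specific parameter tables
#' (see [readIntensityMap()]).
#'
#' @param level metabolic rate, W (200, 300 or 400).
#' @param setting `"indoor"` (exposure uses the indoor WBGT offset) or
#'   `"outdoor"`.
#' @param prodMean,prodSD cumulative-normal loss-curve location/scale,
#'   deg C-WBGT.
#' @param alpha1,alpha2 logistic (Hothaps) workability shape parameters.
#' @return `workIntensity()`: a \linkS4class{WorkIntensity};
#'   `defaultSectorIntensityMap()`: a named list of them.
#' @examples
#' defaultSectorIntensityMap()[["agriculture"]]@level
#' @export
workIntensity <- function(level, setting,
                          prodMean = c(`200` = 34.5, `300` = 32.5,
                                       `400` = 30.5)[[as.character(level)]],
                          prodSD = 4,
                          alpha1 = c(`200` = 35, `300` = 33.5,
                                     `400` = 32)[[as.character(level)]],
                          alpha2 = c(`200` = 10.5, `300` = 7,
                                     `400` = 4)[[as.character(level)]]) {
  new("WorkIntensity", level = level, setting = setting,
      prodMean = prodMean, prodSD = prodSD,
      alpha1 = alpha1, alpha2 = alpha2)
}

#' @rdname workIntensity
#' @export
defaultSectorIntensityMap <- function() {
  list(services     = workIntensity(200, "indoor"),
       industry     = workIntensity(300, "indoor"),
       construction = workIntensity(400, "outdoor"),
       agriculture  = workIntensity(400, "outdoor"))
}

#' WBGT exposure-response functions for work capacity
#'
#' `lossFractionErf()` is the benchmark cumulative-normal loss curve
#' \deqn{L(W) = \tfrac12\left(1 + \mathrm{erf}\!\left(\frac{W -
#'   Prod_{mean}}{Prod_{SD}\sqrt 2}\right)\right),}
#' strictly increasing in WBGT from 0 to 1.  `workabilityHothaps()` is the
#' logistic workability curve used for sensitivity analysis,
#' \deqn{0.1 + \frac{0.9}{1 + (W/\alpha_1)^{\alpha_2}},}
#' which decreases from 1 at W = 0 towards the 0.1 asymptote; its loss
#' complement is 1 - workability.
#'
#' @param wbgt WBGT exposure, deg C-WBGT (nonnegative for the Hothaps form).
#' @param prodMean,prodSD location and scale of the loss curve (prodSD > 0).
#' @param alpha1,alpha2 positive shape parameters.
#' @return Fractions in [0, 1] (workability in (0.1, 1] for the Hothaps
#'   curve).
#' @examples
#' lossFractionErf(32.5, 32.5, 4)   # 0.5 at the curve midpoint
#' workabilityHothaps(32, 32, 4)    # 0.55 at W = alpha1
#' @importFrom pracma erf
#' @export
lossFractionErf <- function(wbgt, prodMean, prodSD) {
  stopifnot(prodSD > 0)
  0.5 * (1 + pracma::erf((wbgt - prodMean) / (prodSD * sqrt(2))))
}

#' @rdname lossFractionErf
#' @export
workabilityHothaps <- function(wbgt, alpha1, alpha2) {
  stopifnot(alpha1 > 0, alpha2 > 0)
  if (any(wbgt < 0)) stop("the Hothaps curve is defined for WBGT >= 0")
  0.1 + 0.9 / (1 + (wbgt / alpha1)^alpha2)
}

#' Daily work-capacity loss under the 4+4+4 approximation
#'
#' The 12-hour workday assigns 4 hours each to WBGT_max, WBGT_mean and their
#' midpoint; the daily loss is the unweighted mean of the exposure-response
#' loss at the three values.  Indoor intensity classes are evaluated at the
#' indoor-adjusted WBGT (outdoor minus the fixed offset).
#'
#' @param wbgt a \linkS4class{WBGTGrid}.
#' @param intensity a \linkS4class{WorkIntensity}.
#' @param fn `"erf"` (benchmark) or `"hothaps"` (loss = 1 - workability).
#' @return Numeric matrix (cells x days) of daily loss fractions in [0, 1].
#' @examples
#' clim <- generateClimate(climateGenConfig(nLat = 2, nLon = 2,
#'                                          startYear = 2000, endYear = 2000))
#' L <- dailyLoss(computeWBGT(clim), workIntensity(400, "outdoor"))
#' range(L)
#' @export
dailyLoss <- function(wbgt, intensity, fn = c("erf", "hothaps")) {
  fn <- match.arg(fn)
  validObject(intensity)
  triplet <- list(wbgtMax(wbgt), wbgtMean(wbgt), wbgtHalf(wbgt))
  if (intensity@setting == "indoor") triplet <- lapply(triplet, wbgtIndoor)
  lossAt <- function(w) switch(fn,
    erf = lossFractionErf(w, intensity@prodMean, intensity@prodSD),
    hothaps = 1 - workabilityHothaps(pmax(w, 0), intensity@alpha1,
                                     intensity@alpha2))
  (lossAt(triplet[[1]]) + lossAt(triplet[[2]]) + lossAt(triplet[[3]])) / 3
}

#' Air-conditioning penetration from climate and income
#'
#' Penetration is a climate-driven saturation level times an income
#' logistic:
#' \deqn{pen = satMax\,(1 - e^{-\max(C - C_0, 0)/s}) \cdot
#'   \mathrm{logit}^{-1}\!\big(k (\log y - \log y_{1/2})\big),}
#' with C the indoor-WBGT climatology: hotter climates saturate at higher
#' penetration, richer populations approach that saturation.  Only indoor
#' work protected by air conditioning escapes heat-induced capacity loss.
#'
#' @param income per-capita income, USD/yr (> 0).
#' @param indoorClim indoor-WBGT warm-season climatology, deg C-WBGT.
#' @param model an \linkS4class{ACModel} from `acModel()`.
#' @return Penetration fraction in [0, 1]; nondecreasing in both arguments.
#' @examples
#' acPenetration(50000, 26, acModel())
#' @importFrom stats plogis
#' @export
acPenetration <- function(income, indoorClim, model = acModel()) {
  validObject(model)
  if (any(income <= 0)) stop("incomes must be > 0")
  sat <- model@satMax * (1 - exp(-pmax(indoorClim - model@climBase, 0) /
                                   model@climScale))
  sat * plogis(model@incomeSlope * (log(income) - log(model@incomeMidpoint)))
}

#' @rdname acPenetration
#' @param satMax asymptotic penetration in the hottest climates, in [0, 1].
#' @param climBase indoor-WBGT climatology with zero cooling demand.
#' @param climScale e-folding scale of the saturation curve, deg C-WBGT.
#' @param incomeMidpoint income at half-saturation, USD/yr.
#' @param incomeSlope logistic steepness per log-income unit.
#' @export
acModel <- function(satMax = 1, climBase = 12, climScale = 8,
                    incomeMidpoint = 20000, incomeSlope = 1.5) {
  new("ACModel", satMax = satMax, climBase = climBase, climScale = climScale,
      incomeMidpoint = incomeMidpoint, incomeSlope = incomeSlope)
}

#' Apply air-conditioning protection to a daily loss
#'
#' Indoor work under air conditioning is protected: the effective loss is
#' (1 - penetration) times the unprotected loss.  Outdoor work is never
#' protected.
#'
#' @param loss daily loss fraction(s) in [0, 1].
#' @param setting `"indoor"` or `"outdoor"`.
#' @param penetration air-conditioning penetration in [0, 1].
#' @return Effective loss fraction(s).
#' @examples
#' effectiveDailyLoss(0.4, "indoor", 0.75)  # 0.1
#' @export
effectiveDailyLoss <- function(loss, setting, penetration) {
  stopifnot(all(loss >= 0 & loss <= 1),
            all(penetration >= 0 & penetration <= 1))
  if (setting == "indoor") (1 - penetration) * loss else loss
}

#' Regional indoor-WBGT warm-season climatology
#'
#' Population-weighted mean of the indoor-adjusted daily mean WBGT over
#' warm-season days, per region; the climate input to [acPenetration()].
#'
#' @param wbgt a \linkS4class{WBGTGrid}.
#' @param popGrid a \linkS4class{PopulationGrid} on the same cells.
#' @return Named numeric, one climatology per region (deg C-WBGT).
#' @export
regionIndoorClimatology <- function(wbgt, popGrid) {
  warm <- warmSeasonMask(rowData(wbgt)$lat, colData(wbgt)$doy)
  wi <- wbgtIndoor(wbgtMean(wbgt))
  cellClim <- rowSums(wi * warm) / pmax(rowSums(warm), 1)
  regs <- sort(unique(popGrid@region))
  vapply(regs, function(r) {
    sel <- popGrid@region == r
    w <- popGrid@pop[sel]
    if (sum(w) == 0) stop("region ", r, " has zero population")
    sum(cellClim[sel] * w) / sum(w)
  }, numeric(1))
}

#' Aggregate daily losses to region-sector labour availability
#'
#' Builds the climate-to-economy bridge \eqn{\gamma^L_{r,s}(t)}: for each
#' sector's work-intensity class, the effective daily loss (after
#' air-conditioning protection for indoor classes) is masked to the
#' hemisphere-specific warm season, then population-weighted over each
#' region's cells.  Outside a cell's warm-season window its contribution is
#' zero.
#'
#' @param wbgt a \linkS4class{WBGTGrid}.
#' @param popGrid a \linkS4class{PopulationGrid} on the same cells.
#' @param intensityMap named list of \linkS4class{WorkIntensity}, one per
#'   sector.
#' @param acPen named numeric, air-conditioning penetration per region
#'   (default 0 everywhere).
#' @param fn exposure-response function, `"erf"` or `"hothaps"`.
#' @return A \linkS4class{LabourAvailability} with one column per
#'   region-sector pair (region label, ".", sector label).
#' @examples
#' cfg <- climateGenConfig(nLat = 2, nLon = 4, startYear = 2000,
#'                         endYear = 2000)
#' wb <- computeWBGT(generateClimate(cfg))
#' pg <- generatePopulation(populationGenConfig(nLat = 2, nLon = 4,
#'                                              nRegions = 2))
#' la <- aggregateGamma(wb, pg, defaultSectorIntensityMap())
#' dim(gammaSeries(la))
#' @export
aggregateGamma <- function(wbgt, popGrid, intensityMap,
                           acPen = NULL, fn = "erf") {
  lat <- rowData(wbgt)$lat
  if (length(popGrid@pop) != nrow(wbgt))
    stop("population grid and WBGT grid have different cell counts")
  regs <- sort(unique(popGrid@region))
  if (is.null(acPen)) acPen <- setNames(rep(0, length(regs)), regs)
  if (!all(regs %in% names(acPen))) stop("acPen must cover every region")
  warm <- warmSeasonMask(lat, colData(wbgt)$doy)
  nd <- ncol(wbgt)

  cols <- list(); region <- character(); sector <- character()
  for (s in names(intensityMap)) {
    intensity <- intensityMap[[s]]
    L <- dailyLoss(wbgt, intensity, fn)
    for (r in regs) {
      sel <- popGrid@region == r
      w <- popGrid@pop[sel]
      if (sum(w) == 0) stop("region ", r, " has zero population")
      eff <- effectiveDailyLoss(L[sel, , drop = FALSE], intensity@setting,
                                acPen[[r]])
      eff <- eff * warm[sel, , drop = FALSE]
      g <- as.numeric(crossprod(w, eff) / sum(w))
      cols[[paste(r, s, sep = ".")]] <- g
      region <- c(region, r); sector <- c(sector, s)
    }
  }
  gamma <- do.call(cbind, cols)
  new("LabourAvailability", gamma = gamma,
      year = as.integer(colData(wbgt)$year),
      doy = as.integer(colData(wbgt)$doy),
      region = region, sector = sector)
}
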