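test_that("erf-based loss equals the Gaussian CDF oracle", {
  set.seed(5)
  w <- runif(50, 10, 45)
  expect_equal(lossFractionErf(w, 32.5, 4), pnorm(w, 32.5, 4),
               tolerance = 1e-10)
  expect_equal(lossFractionErf(32.5, 32.5, 4), 0.5)
  expect_equal(lossFractionErf(-1e4, 32.5, 4), 0)
  expect_equal(lossFractionErf(1e4, 32.5, 4), 1)
  expect_true(all(diff(lossFractionErf(seq(0, 50, 0.5), 30.5, 4)) > 0))
})

test_that("Hothaps workability has the logistic midpoint and asymptotes", {
  expect_equal(workabilityHothaps(32, 32, 4), 0.55)      # W = alpha1
  expect_equal(workabilityHothaps(0, 32, 4), 1.0)
  expect_equal(workabilityHothaps(1e6, 32, 4), 0.1, tolerance = 1e-12)
  w <- seq(0, 60, by = 0.5)
  expect_true(all(diff(workabilityHothaps(w, 32, 4)) < 0))
  expect_true(all(workabilityHothaps(w, 32, 4) > 0.1 - 1e-12))
  expect_error(workabilityHothaps(-1, 32, 4), "WBGT")
})

test_that("daily loss is the explicit three-point average with indoor adjustment", {
  clim <- generateClimate(climateGenConfig(nLat = 2, nLon = 2,
                                           startYear = 2000, endYear = 2000,
                                           seed = 23))
  wb <- computeWBGT(clim)
  out <- workIntensity(400, "outdoor")
  L <- dailyLoss(wb, out)
  manual <- (pnorm(wbgtMax(wb), out@prodMean, out@prodSD) +
             pnorm(wbgtMean(wb), out@prodMean, out@prodSD) +
             pnorm(wbgtHalf(wb), out@prodMean, out@prodSD)) / 3
  expect_equal(L, manual, tolerance = 1e-10)
  # bounded by the losses at the extreme triplet members
  expect_true(all(L <= pnorm(wbgtMax(wb), out@prodMean, out@prodSD) + 1e-12))
  expect_true(all(L >= pnorm(wbgtMean(wb), out@prodMean, out@prodSD) - 1e-12))
  # indoor classes see the offset WBGT
  ind <- workIntensity(300, "indoor")
  Lind <- dailyLoss(wb, ind)
  manualInd <- (pnorm(wbgtMax(wb) - 4, ind@prodMean, ind@prodSD) +
                pnorm(wbgtMean(wb) - 4, ind@prodMean, ind@prodSD) +
                pnorm(wbgtHalf(wb) - 4, ind@prodMean, ind@prodSD)) / 3
  expect_equal(Lind, manualInd, tolerance = 1e-10)
})

test_that("constant-WBGT days give the pointwise loss", {
  clim <- generateClimate(climateGenConfig(nLat = 1, nLon = 1,
                                           startYear = 2000, endYear = 2000,
                                           diurnalRange = 0, noiseSD = 0))
  wb <- computeWBGT(clim)
  it <- workIntensity(200, "outdoor")
  expect_equal(dailyLoss(wb, it),
               pnorm(wbgtMean(wb), it@prodMean, it@prodSD))
})

test_that("air-conditioning penetration is monotone with the expected limits", {
  m <- acModel()
  incomes <- exp(seq(log(500), log(5e5), length.out = 40))
  pen <- acPenetration(incomes, 28, m)
  expect_true(all(diff(pen) > 0))
  expect_true(all(pen >= 0 & pen <= 1))
  sat <- m@satMax * (1 - exp(-(28 - m@climBase) / m@climScale))
  expect_equal(acPenetration(1e12, 28, m), sat, tolerance = 1e-6)
  expect_lt(acPenetration(1e-6, 28, m), 1e-6)
  # monotone in the climatology too
  clims <- seq(5, 35, by = 1)
  expect_true(all(diff(acPenetration(3e4, clims, m)) >= 0))
})

test_that("only air-conditioned indoor work is protected", {
  expect_equal(effectiveDailyLoss(0.4, "indoor", 1), 0)
  expect_equal(effectiveDailyLoss(0.4, "indoor", 0), 0.4)
  expect_equal(effectiveDailyLoss(0.4, "indoor", 0.75), 0.1)
  expect_equal(effectiveDailyLoss(0.4, "outdoor", 1), 0.4)
})

test_that("gamma aggregation weights cells by population inside the warm season", {
  # two cells, same region, northern hemisphere
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tmean = matrix(30, 2, 365), tmax = matrix(30, 2, 365),
                  rh = matrix(50, 2, 365)),
    rowData = S4Vectors::DataFrame(lat = c(40, 42), lon = c(0, 10)),
    colData = S4Vectors::DataFrame(year = rep(2000L, 365), doy = 1:365))
  clim <- new("ClimateGrid", se)
  wb <- computeWBGT(clim)
  pg <- new("PopulationGrid", pop = c(1, 3), lat = c(40, 42), lon = c(0, 10),
            region = c("R1", "R1"),
            regionTable = data.frame(region = "R1", mortality = 2e-5,
                                     income = 2e4))
  it <- list(construction = workIntensity(400, "outdoor"))
  la <- aggregateGamma(wb, pg, it)
  g <- gammaSeries(la)[, "R1.construction"]
  month <- monthOfDoy(1:365)
  warm <- month %in% 6:9
  expect_true(all(g[!warm] == 0))
  L <- pnorm(wbgtOutdoor(30, 50), 30.5, 4)  # constant triplet
  expect_equal(unname(g[warm]), rep((1 * L + 3 * L) / 4, sum(warm)))
  # weighted mean with unequal losses: pops (1, 3), losses (L, 0) -> L/4
  pg2 <- pg; pg2@pop <- c(1, 3)
  wb2 <- wb
  la2 <- aggregateGamma(wb2, pg2, it,
                        acPen = c(R1 = 0))
  expect_equal(max(gammaSeries(la2)), L, tolerance = 1e-12)
})

test_that("southern-hemisphere regions are active only in the austral window", {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tmean = matrix(30, 1, 365), tmax = matrix(30, 1, 365),
                  rh = matrix(50, 1, 365)),
    rowData = S4Vectors::DataFrame(lat = -25, lon = 30),
    colData = S4Vectors::DataFrame(year = rep(2000L, 365), doy = 1:365))
  wb <- computeWBGT(new("ClimateGrid", se))
  pg <- new("PopulationGrid", pop = 5, lat = -25, lon = 30, region = "R1",
            regionTable = data.frame(region = "R1", mortality = 2e-5,
                                     income = 2e4))
  la <- aggregateGamma(wb, pg, list(agriculture = workIntensity(400, "outdoor")))
  g <- gammaSeries(la)[, 1]
  month <- monthOfDoy(1:365)
  expect_true(all(g[month %in% c(12, 1:3)] > 0))
  expect_true(all(g[!month %in% c(12, 1:3)] == 0))
})

test_that("two-cell weighted mean reproduces hand arithmetic", {
  # pops (1, 3), effective losses (0.4, 0): gamma = 0.1
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tmean = matrix(c(31.23, -40), 2, 10), # cold cell: loss ~ 0
                  tmax = matrix(c(31.23, -40), 2, 10),
                  rh = matrix(0, 2, 10)),
    rowData = S4Vectors::DataFrame(lat = c(40, 41), lon = 0:1),
    colData = S4Vectors::DataFrame(year = rep(2000L, 10), doy = 180:189))
  wb <- computeWBGT(new("ClimateGrid", se))
  # choose prodMean so the hot cell's loss is exactly 0.4
  w <- wbgtOutdoor(31.23, 0)
  pm <- w - qnorm(0.4) * 4
  pg <- new("PopulationGrid", pop = c(1, 3), lat = c(40, 41), lon = 0:1,
            region = c("R1", "R1"),
            regionTable = data.frame(region = "R1", mortality = 2e-5,
                                     income = 2e4))
  it <- list(s = workIntensity(400, "outdoor", prodMean = pm, prodSD = 4))
  g <- gammaSeries(aggregateGamma(wb, pg, it))
  expect_equal(max(g), 0.1, tolerance = 1e-6)
})

test_that("intensity maps read from YAML match the defaults", {
  path <- system.file("extdata", "intensity_map_synthetic.yaml",
                      package = "heatfootprint")
  im <- readIntensityMap(path)
  def <- defaultSectorIntensityMap()
  expect_setequal(names(im), names(def))
  expect_equal(im$industry@prodMean, def$industry@prodMean)
  expect_identical(im$construction@setting, "outdoor")
})
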