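test_that("excess deaths follow the multiplicative attribution formula", {
  expect_equal(excessDeaths(1e6, 2e-5, 1.5, 10), 100)
  expect_equal(excessDeaths(5e5, 2e-5, 1, 30), 0)       # null effect at RR = 1
  base <- excessDeaths(1e6, 2e-5, 1.5, 10)
  expect_equal(excessDeaths(2e6, 2e-5, 1.5, 10), 2 * base)
  expect_equal(excessDeaths(1e6, 4e-5, 1.5, 10), 2 * base)
  expect_equal(excessDeaths(1e6, 2e-5, 2.0, 10), 2 * base)
  expect_equal(excessDeaths(1e6, 2e-5, 1.5, 20), 2 * base)
  expect_error(excessDeaths(-1, 2e-5, 1.5, 10), "nonnegative")
  expect_error(excessDeaths(1e6, 2e-5, 0.9, 10), "risks")
})

test_that("death counts are additive under cell splitting", {
  whole <- excessDeaths(1e6, 3e-5, 1.4, 12)
  parts <- excessDeaths(c(4e5, 6e5), 3e-5, 1.4, 12)
  expect_equal(sum(parts), whole)
})

test_that("VSL transfers with income elasticity and anchors at the anchor income", {
  p <- vslParams()
  expect_equal(vslForRegion(65000, params = p), 11e6)
  expect_equal(vslForRegion(32500, params = p), 5.5e6)
  half <- vslParams(incomeElasticity = 0.5)
  expect_equal(vslForRegion(65000 / 4, params = half), 11e6 / 2)
  expect_error(vslForRegion(0, params = p), "income")
})

test_that("equal-world mode applies the population-weighted mean VSL", {
  p <- vslParams(anchorVSL = 8, anchorIncome = 100, incomeElasticity = 1,
                 mode = "equal_world")
  # incomes give income-scaled VSLs (8, 4); populations (1, 3) -> mean 5
  v <- vslForRegion(c(100, 50), pop = c(1, 3), params = p)
  expect_equal(v, c(5, 5))
  # with equal incomes the world total of deaths x VSL is conserved
  pi <- vslParams(mode = "income_scaled")
  pe <- vslParams(mode = "equal_world")
  d <- c(10, 20)
  vi <- vslForRegion(c(40000, 40000), params = pi)
  ve <- vslForRegion(c(40000, 40000), pop = c(5, 9), params = pe)
  expect_equal(sum(d * vi), sum(d * ve))
})

test_that("health loss valuation multiplies deaths by VSL and scales by GDP", {
  h <- healthLossValue(c(A = 100, B = 0), c(A = 1e6, B = 2e6),
                       c(A = 1e10, B = 1e10))
  expect_equal(h$loss, c(1e8, 0))
  expect_equal(h$lossShareGDP, c(0.01, 0))
  expect_error(healthLossValue(c(A = 1), c(B = 1), c(A = 1)), "regions")
})

test_that("climate-zone helper produces four populated quartile zones", {
  clim <- generateClimate(climateGenConfig(nLat = 4, nLon = 8,
                                           startYear = 2000, endYear = 2002,
                                           seed = 31))
  z <- assignClimateZones(clim, c(2000, 2002))
  expect_setequal(sort(unique(z)), 1:4)
  expect_length(z, 32)
})

test_that("regional aggregation sums cell-level deaths without double counting", {
  cfg <- climateGenConfig(nLat = 2, nLon = 4, startYear = 2000,
                          endYear = 2005, seed = 17)
  clim <- generateClimate(cfg)
  hw <- detectHeatwaves(clim, heatwaveDefinition(90, 2, c(2000, 2004)))
  pg <- generatePopulation(populationGenConfig(nLat = 2, nLon = 4,
                                               nRegions = 2, totalPop = 1e6,
                                               seed = 8))
  zones <- rep(1:4, 2)
  rr <- c("1" = 1.1, "2" = 1.2, "3" = 1.3, "4" = 1.4)
  reg <- regionalExcessDeaths(pg, hw, zones, rr, years = 2005)
  mr <- pg@regionTable$mortality[match(pg@region, pg@regionTable$region)]
  cell <- excessDeaths(pg@pop, mr, rr[as.character(zones)],
                       hwn(hw)[, "2005"])
  expect_equal(unname(reg), unname(tapply(cell, pg@region, sum)))
  expect_equal(sum(reg), sum(cell))
})

test_that("RR tables read from file are validated", {
  path <- system.file("extdata", "rr_table_synthetic.csv",
                      package = "heatfootprint")
  rr <- readRRTable(path)
  expect_named(rr, c("1", "2", "3", "4"))
  expect_true(all(rr >= 1))
})
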