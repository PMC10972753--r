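# Small helper: wrap a cells x days matrix as a ClimateGrid over given years.
gridFromMatrix <- function(tm, startYear) {
  nYears <- ncol(tm) / 365
  cal <- noleapCalendar(startYear, startYear + nYears - 1)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tmean = tm, tmax = tm + 4,
                  rh = matrix(50, nrow(tm), ncol(tm))),
    rowData = S4Vectors::DataFrame(lat = seq_len(nrow(tm)), lon = 0),
    colData = S4Vectors::DataFrame(year = cal$year, doy = cal$doy))
  new("ClimateGrid", se)
}

test_that("static threshold matches a brute-force percentile oracle", {
  set.seed(1)
  tm <- matrix(rnorm(200 * 365, 20, 5), 200, 365)
  g <- gridFromMatrix(tm, 2000)
  for (p in c(50, 90, 95, 97.5)) {
    thr <- staticThreshold(g, p, c(2000, 2000))
    oracle <- apply(tm, 1, bruteforcePercentile, p = p)
    expect_equal(thr, oracle, tolerance = 1e-12)
  }
  cst <- gridFromMatrix(matrix(7, 1, 365), 2000)
  expect_equal(staticThreshold(cst, 95, c(2000, 2000)), 7)
})

test_that("detector equals the brute-force run-length oracle on random series", {
  set.seed(42)
  n <- 300
  tm <- matrix(rnorm(n * 365, 20, 5), n, 365)
  g <- gridFromMatrix(tm, 2010)
  for (minRun in c(1, 2, 4)) {
    defn <- heatwaveDefinition(minRun = minRun, baselineYears = c(2010, 2010))
    thr <- staticThreshold(g, 95, c(2010, 2010))
    hw <- detectHeatwaves(g, defn, threshold = thr)
    oracle <- t(vapply(seq_len(n), function(i)
      bruteforceHeatwaveMask(tm[i, ] > thr[i], minRun), logical(365)))
    expect_identical(unname(eventMask(hw)), oracle)
    expect_equal(unname(hwn(hw)[, 1]), rowSums(oracle))
  }
})

test_that("HWN is monotone nonincreasing in percentile and minimum run", {
  set.seed(3)
  tm <- matrix(rnorm(50 * 730, 22, 4), 50, 730)
  g <- gridFromMatrix(tm, 2000)
  base <- c(2000, 2000)
  total <- function(p, r)
    sum(hwn(detectHeatwaves(g, heatwaveDefinition(p, r, base))))
  expect_true(total(90, 2) >= total(95, 2))
  expect_true(total(95, 2) >= total(97.5, 2))
  expect_true(total(95, 2) >= total(95, 3))
  expect_true(total(95, 3) >= total(95, 5))
})

test_that("isolated exceedances are dropped and runs cross year boundaries additively", {
  tm <- matrix(10, 1, 730)
  tm[1, 363:368] <- 30       # run spanning the new year
  tm[1, 100] <- 30           # isolated single day
  g <- gridFromMatrix(tm, 2000)
  hw <- detectHeatwaves(g, heatwaveDefinition(95, 2, c(2000, 2001)),
                        threshold = 25)
  expect_equal(unname(hwn(hw)[1, ]), c(3, 3))  # 363-365 and 1-3
  expect_false(eventMask(hw)[1, 100])
  hw1 <- detectHeatwaves(g, heatwaveDefinition(95, 2, c(2000, 2001)),
                         threshold = 35)
  expect_true(all(hwn(hw1) == 0))
})

test_that("ties at the threshold are not exceedances (strict comparison)", {
  tm <- matrix(25, 1, 365)
  g <- gridFromMatrix(tm, 2000)
  hw <- detectHeatwaves(g, heatwaveDefinition(95, 2, c(2000, 2000)),
                        threshold = 25)
  expect_true(all(hwn(hw) == 0))
})

test_that("dynamic thresholds approximate static under stationarity and never use the target year", {
  set.seed(9)
  tm <- matrix(rnorm(20 * 365 * 8, 20, 5), 20)
  g <- gridFromMatrix(tm, 2000)
  dyn <- dynamicThreshold(g, 95, baselineStart = 2000, targetYears = 2007)
  sta <- staticThreshold(g, 95, c(2000, 2006))
  expect_equal(unname(dyn[, "2007"]), sta, tolerance = 1e-12)  # same window
  expect_error(dynamicThreshold(g, 95, 2000, targetYears = 2000), "after")
})

test_that("monotone warming with zero noise gives strictly increasing dynamic thresholds", {
  cfg <- climateGenConfig(nLat = 1, nLon = 2, startYear = 2000,
                          endYear = 2010, noiseSD = 0, warmingRate = 2)
  g <- generateClimate(cfg)
  thr <- dynamicThreshold(g, 95, baselineStart = 2000)
  expect_true(all(apply(thr, 1, diff) > 0))
})

test_that("dynamic detection only scores years after the baseline start", {
  cfg <- climateGenConfig(nLat = 1, nLon = 1, startYear = 2000,
                          endYear = 2005, seed = 12)
  g <- generateClimate(cfg)
  hw <- detectHeatwaves(g, heatwaveDefinition(95, 2, c(2000, 2005),
                                              dynamic = TRUE))
  expect_true(all(eventMask(hw)[, SummarizedExperiment::colData(g)$year == 2000] == FALSE))
})
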