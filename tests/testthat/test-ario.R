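test_that("calibration satisfies the accounting identities", {
  mrio <- generateMRIO(mrioGenConfig(3, 2, seed = 14))
  net <- calibrateNetwork(mrio, stepsPerYear = 365)
  expect_equal(colSums(net@a) + net@b, rep(1, 6), tolerance = 1e-10,
               ignore_attr = TRUE)
  # baseline orders reproduce the (per-step) MRIO flows
  expect_equal(net@Zbar * 365, flowMatrix(mrio))
  expect_equal(net@Fbar * 365, finalDemand(mrio))
  expect_equal(net@vaBar * 365, unname(valueAdded(mrio)))
  # per-step household demand aggregates final demand by product
  expect_equal(colSums(net@HD), colSums(finalDemand(mrio)) / 365)
})

test_that("a firm with no intermediate use has b = 1", {
  m <- chainMRIO()
  net <- calibrateNetwork(m, stepsPerYear = 1)
  up <- which(net@sector == "up")
  expect_equal(unname(net@b[up]), 1)
  expect_equal(sum(net@a[, up]), 0)
})

test_that("capacity components follow their closed forms", {
  net <- smallNet()
  st <- initialState(net, simConfig(horizon = 10, nTarget = 2))
  # labour/capital: (1 - gamma) x xbar; inventory: S / a with a = 0 unconstrained
  out <- stepFootprint(net, st, gL = rep(0.25, 6), gK = rep(0, 6),
                       config = simConfig(horizon = 10, nTarget = 2))
  expect_equal(unname(out$xa), pmin(0.75 * net@xbar, unname(st$TOD)),
               tolerance = 1e-12)
  expect_equal(unname(out$xmax), 0.75 * net@xbar, tolerance = 1e-12)
})

test_that("inventory constraints stop production when stocks run out", {
  net <- calibrateNetwork(chainMRIO(), stepsPerYear = 1)
  st <- initialState(net, simConfig(nTarget = 0))   # zero inventories
  out <- stepFootprint(net, st, gL = c(0, 0), gK = c(0, 0),
                       config = simConfig(nTarget = 0))
  down <- which(net@sector == "down")
  expect_equal(unname(out$xa[down]), 0)                     # S = 0, a > 0 halts
  up <- which(net@sector == "up")
  expect_equal(unname(out$xa[up]), unname(net@xbar[up]))            # no inputs needed
})

test_that("the no-shock trajectory is an exact fixed point with zero footprints", {
  net <- smallNet(nR = 3, nS = 2, seed = 19, steps = 100)
  cfg <- simConfig(horizon = 100)
  fp <- runFootprint(net, shockSeries(net, 100), cfg)
  scale <- max(net@vaBar) * 100
  expect_lt(max(abs(tef(fp))) / scale, 1e-8)
  expect_lt(max(abs(def(fp))) / scale, 1e-8)
  expect_lt(max(abs(pef(fp))) / scale, 1e-8)
  # state drift: outputs stay at baseline every step
  expect_lt(max(abs(fp@vaA - matrix(net@vaBar, 100, 6, byrow = TRUE))) /
              max(net@vaBar), 1e-8)
})

test_that("allocations are conserved and inventories stay nonnegative under random shocks", {
  set.seed(77)
  net <- smallNet(nR = 3, nS = 3, seed = 23)
  cfg <- simConfig(horizon = 1, nTarget = 5)
  st <- initialState(net, cfg)
  N <- length(net@xbar)
  for (t in 1:60) {
    gL <- pmin(pmax(runif(N, -0.3, 0.8), 0), 1)   # many zeros, some severe
    gK <- pmin(pmax(runif(N, -0.6, 0.4), 0), 1)
    st <- stepFootprint(net, st, gL, gK, config = cfg)
    alloc <- rowSums(st$FRC) + rowSums(st$HRC)
    expect_equal(alloc, st$xa, tolerance = 1e-12)
    expect_true(all(st$S >= 0))
    expect_true(all(st$FOD >= 0) && all(st$HOD >= 0))
  }
})

test_that("proportional rationing splits output in proportion to orders", {
  net <- calibrateNetwork(chainMRIO(), stepsPerYear = 1)
  st <- initialState(net, simConfig(nTarget = 2))
  # upstream firm halves its output: orders were (firm 40, household 60)
  out <- stepFootprint(net, st, gL = c(0.5, 0), gK = c(0, 0),
                       config = simConfig(nTarget = 2))
  up <- which(net@sector == "up")
  expect_equal(unname(out$xa[up]), 50)
  expect_equal(unname(out$FRC[up, net@sector == "down"]), 20)  # 40/100 x 50
  expect_equal(unname(out$HRC[up, 1]), 30)                     # 60/100 x 50
})

test_that("an isolated firm's loss is the closed-form direct loss", {
  # three firms; C trades with nobody (its own final demand only)
  firm <- c("R1.a", "R1.b", "R2.c")
  Z <- matrix(0, 3, 3, dimnames = list(firm, firm))
  Z["R1.a", "R1.b"] <- 30
  F <- matrix(c(70, 100, 0, 0, 0, 80), 3, 2,
              dimnames = list(firm, c("R1", "R2")))
  m <- new("MRIOTable", Z = Z, F = F,
           va = c(100, 70, 80), x = c(100, 100, 80),
           region = c("R1", "R1", "R2"), sector = c("a", "b", "c"))
  net <- calibrateNetwork(m, stepsPerYear = 1)
  g <- matrix(0, 20, 3); g[1:10, 3] <- 0.1
  fp <- runFootprint(net, shockSeries(net, 20, gammaL = g),
                     simConfig(horizon = 20))
  expect_equal(unname(tef(fp)["R2.c"]), 0.1 * 80 * 10, tolerance = 1e-10)
  expect_equal(unname(def(fp)["R2.c"]), 0.1 * 80 * 10, tolerance = 1e-10)
  expect_equal(unname(pef(fp)["R2.c"]), 0, tolerance = 1e-10)
})

test_that("connected networks satisfy TEF >= DEF >= 0 and PEF >= 0", {
  net <- smallNet(nR = 4, nS = 3, seed = 31, steps = 80)
  N <- length(net@xbar)
  g <- matrix(0, 80, N); g[1:40, 1:6] <- 0.35
  fp <- runFootprint(net, shockSeries(net, 80, gammaL = g),
                     simConfig(horizon = 80, nTarget = 10))
  expect_true(all(def(fp) >= -1e-9))
  expect_true(all(pef(fp) >= -1e-9))
  expect_true(sum(tef(fp)) >= sum(def(fp)))
  # actual production never exceeds capacity nor baseline
  expect_true(all(fp@vaA <= fp@vaMax + 1e-9))
  expect_true(all(fp@vaMax <= matrix(net@vaBar, 80, N, byrow = TRUE) + 1e-9))
})

test_that("a one-step shock is absorbed by inventory buffers downstream", {
  net <- calibrateNetwork(chainMRIO(), stepsPerYear = 1)
  g <- matrix(0, 4, 2); g[1, net@sector == "up"] <- 1
  fp <- runFootprint(net, shockSeries(net, 4, gammaL = g),
                     simConfig(horizon = 4, nTarget = 2))
  down <- which(net@sector == "down")
  expect_equal(unname(fp@vaA[1, down]), unname(net@vaBar[down]))  # buffer holds
})

test_that("substitution exponent reallocates orders towards spare capacity", {
  # two identical suppliers of the same product; one at half capacity
  firm <- c("R1.up", "R2.up", "R1.down")
  Z <- matrix(0, 3, 3, dimnames = list(firm, firm))
  Z[c("R1.up", "R2.up"), "R1.down"] <- 20
  F <- matrix(c(80, 0, 0, 0, 80, 100), 3, 2,
              dimnames = list(firm, c("R1", "R2")))
  m <- new("MRIOTable", Z = Z, F = F,
           va = c(100, 100, 60), x = c(100, 100, 100),
           region = c("R1", "R2", "R1"), sector = c("up", "up", "down"))
  net <- calibrateNetwork(m, stepsPerYear = 1)
  st <- initialState(net, simConfig(nTarget = 2))
  run1 <- stepFootprint(net, st, gL = c(0.5, 0, 0), gK = rep(0, 3),
                        config = simConfig(nTarget = 2,
                                           substitutionExponent = 1))
  ord <- run1$FOD[c("R1.up", "R2.up"), "R1.down"]
  expect_equal(unname(ord[2] / ord[1]), 2, tolerance = 1e-10)  # 2:1 split
  run0 <- stepFootprint(net, st, gL = c(0.5, 0, 0), gK = rep(0, 3),
                        config = simConfig(nTarget = 2,
                                           substitutionExponent = 0))
  ord0 <- run0$FOD[c("R1.up", "R2.up"), "R1.down"]
  expect_equal(unname(ord0[1]), unname(ord0[2]))  # fixed baseline shares
  # a supplier with zero baseline flow never receives orders
  expect_equal(sum(run1$FOD[, c("R1.up", "R2.up")]), 0)
})

test_that("orders fall back to baseline shares when all suppliers are down", {
  firm <- c("R1.up", "R2.up", "R1.down")
  Z <- matrix(0, 3, 3, dimnames = list(firm, firm))
  Z["R1.up", "R1.down"] <- 30
  Z["R2.up", "R1.down"] <- 10
  F <- matrix(c(70, 0, 0, 0, 90, 100), 3, 2,
              dimnames = list(firm, c("R1", "R2")))
  m <- new("MRIOTable", Z = Z, F = F,
           va = c(100, 100, 60), x = c(100, 100, 100),
           region = c("R1", "R2", "R1"), sector = c("up", "up", "down"))
  net <- calibrateNetwork(m, stepsPerYear = 1)
  st <- initialState(net, simConfig(nTarget = 2))
  out <- stepFootprint(net, st, gL = c(1, 1, 0), gK = rep(0, 3),
                       config = simConfig(nTarget = 2))
  ord <- out$FOD[c("R1.up", "R2.up"), "R1.down"]
  expect_equal(unname(ord[1] / ord[2]), 3, tolerance = 1e-10)  # 30:10 baseline
  expect_gt(sum(ord), 0)
})

test_that("the simulator reproduces the hand-unrolled two-firm trajectory", {
  net <- calibrateNetwork(chainMRIO(), stepsPerYear = 1)
  up <- which(net@sector == "up"); down <- which(net@sector == "down")
  cfg <- simConfig(horizon = 5, nTarget = 2)
  st <- initialState(net, cfg)
  oracle <- unrollChainOracle(c(0.5, 0.5), 5, n = 2)
  for (t in 1:5) {
    g <- c(0, 0); if (t <= 2) g[up] <- 0.5
    st <- stepFootprint(net, st, g, c(0, 0), config = cfg)
    o <- oracle[[t]]
    expect_equal(unname(st$xa[up]), o$xaA, tolerance = 1e-12)
    expect_equal(unname(st$xa[down]), o$xaB, tolerance = 1e-12)
    expect_equal(unname(st$S[which(net@products == "up"), down]), o$S,
                 tolerance = 1e-12)
    expect_equal(unname(st$FOD[up, down]), o$FOD, tolerance = 1e-12)
    expect_equal(unname(st$TOD[up]), o$TODA, tolerance = 1e-12)
    expect_equal(unname(st$TOD[down]), o$TODB, tolerance = 1e-12)
  }
})

test_that("footprint accounting matches the unrolled value-added series", {
  net <- calibrateNetwork(chainMRIO(), stepsPerYear = 1)
  fp <- runFootprint(net, shockSeries(net, 5, gammaL = {
    g <- matrix(0, 5, 2); g[1:2, net@sector == "up"] <- 0.5; g
  }), simConfig(horizon = 5, nTarget = 2))
  oracle <- unrollChainOracle(c(0.5, 0.5), 5, n = 2)
  vaA <- sapply(oracle, function(o) c(o$vaA, o$vaB))
  vaM <- sapply(oracle, function(o) c(o$vamaxA, o$vamaxB))
  up <- which(net@sector == "up"); down <- which(net@sector == "down")
  expect_equal(unname(tef(fp)[c(up, down)]),
               c(100, 60) * 5 - rowSums(vaA), tolerance = 1e-10)
  expect_equal(unname(def(fp)[c(up, down)]),
               c(100, 60) * 5 - rowSums(vaM), tolerance = 1e-10)
  expect_equal(tef(fp), def(fp) + pef(fp))
})
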