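## Independent oracles used across the suite.  These are deliberately
## written as plain, slow, scalar code so they share nothing with the
## package implementations they check.

## Day-by-day scan marking days inside exceedance runs of >= minRun days.
bruteforceHeatwaveMask <- function(exceed, minRun) {
  n <- length(exceed)
  mask <- logical(n)
  i <- 1
  while (i <= n) {
    if (exceed[i]) {
      j <- i
      while (j < n && exceed[j + 1]) j <- j + 1
      if (j - i + 1 >= minRun) mask[i:j] <- TRUE
      i <- j + 1
    } else i <- i + 1
  }
  mask
}

## Sort-and-interpolate percentile (linear interpolation between closest
## order statistics), written out by hand.
bruteforcePercentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

## A hand-built balanced two-firm chain: upstream firm A sells 40 to
## downstream firm B and 60 to the household; B sells 100 to the household.
chainMRIO <- function() {
  firm <- c("R1.up", "R1.down")
  Z <- matrix(c(0, 0, 40, 0), 2, 2, dimnames = list(firm, firm))
  F <- matrix(c(60, 100), 2, 1, dimnames = list(firm, "R1"))
  new("MRIOTable", Z = Z, F = F,
      va = c(R1.up = 100, R1.down = 60), x = c(R1.up = 100, R1.down = 100),
      region = c("R1", "R1"), sector = c("up", "down"))
}

## Scalar unrolling of the chain dynamics under a labour shock on the
## upstream firm: follows the update rules step by step with explicit
## arithmetic (inventory target n steps of cover, one step per year unit).
unrollChainOracle <- function(gA, horizon, n = 2) {
  a <- 0.4; bB <- 0.6; xbar <- c(A = 100, B = 100)
  S <- n * a * 100          # B's inventory of A's product
  FOD <- 40; HODA <- 60; HODB <- 100
  TODA <- 100; TODB <- 100
  out <- list()
  for (t in seq_len(horizon)) {
    g <- if (t <= length(gA)) gA[t] else 0
    xmaxA <- (1 - g) * 100
    xmaxB <- min(100, S / a)
    xaA <- min(xmaxA, TODA)
    xaB <- min(xmaxB, TODB)
    Smid <- S - a * xaB
    ## orders (pre-restore inventory position)
    gap <- max(n * a * xmaxB - Smid, 0)
    FODnew <- gap                      # single supplier: full gap to A
    ## allocation of A's output against last step's orders
    totA <- FOD + HODA
    FRC <- if (totA > 0) FOD / totA * xaA else 0
    S <- Smid + FRC
    out[[t]] <- list(xaA = xaA, xaB = xaB, S = S, FOD = FODnew,
                     TODA = FODnew + 60, TODB = 100,
                     vaA = 1 * xaA, vaB = bB * xaB,
                     vamaxA = min(xmaxA, 100), vamaxB = bB * min(xmaxB, 100))
    FOD <- FODnew
    TODA <- FODnew + 60
    TODB <- 100
  }
  out
}

## Small calibrated network + uniform-shock runner used by several tests.
smallNet <- function(nR = 3, nS = 2, seed = 11, steps = 50) {
  calibrateNetwork(generateMRIO(mrioGenConfig(nR, nS, seed = seed)),
                   stepsPerYear = steps)
}
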