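#' Calibrate the supply-chain network from a balanced MRIO table
#'
#' Treats each region-sector pair as a firm and each region as one
#' representative household.  Annual flows are divided by `stepsPerYear` so
#' the per-step baseline is the simulator's equilibrium: input coefficients
#' \eqn{a_i^p = \bar z_i^p / \bar x_i} (product classes are sectors,
#' aggregated over supplier regions), value-added coefficients
#' \eqn{b_i = \bar{va}_i / \bar x_i}, baseline orders equal to baseline
#' flows, and baseline household demand per product.  By construction
#' \eqn{\sum_p a_i^p + b_i = 1} for every firm and one no-shock step
#' reproduces the equilibrium exactly.
#'
#' @param x a balanced \linkS4class{MRIOTable}.
#' @param stepsPerYear number of simulation steps the annual table is split
#'   into (default 365 daily steps).
#' @param ... unused.
#' @return A \linkS4class{CalibratedNetwork}.
#' @examples
#' net <- calibrateNetwork(generateMRIO(mrioGenConfig(2, 2, seed = 5)))
#' max(abs(colSums(net@a) + net@b - 1))
#' @export
setMethod("calibrateNetwork", "MRIOTable", function(x, stepsPerYear = 365, ...) {
  validObject(x)
  if (.mrioResiduals(x@Z, x@F, x@va, x@x) > 1e-6)
    stop("MRIO table is unbalanced (relative residual > 1e-6)")
  if (any(x@x <= 0)) stop("zero-output firm cannot be calibrated")
  products <- unique(x@sector)
  sectorIndex <- match(x@sector, products)
  N <- length(x@x)
  ## aggregate supplier flows into product classes: a[p, i]
  a <- rowsum(x@Z / rep(x@x, each = N), sectorIndex)
  a <- matrix(as.numeric(a), nrow = length(products),
              dimnames = list(products, names(x@x)))
  b <- as.numeric(x@va / x@x)
  Zbar <- x@Z / stepsPerYear
  Fbar <- x@F / stepsPerYear
  HD <- rowsum(Fbar, sectorIndex)
  HD <- matrix(as.numeric(HD), nrow = length(products),
               dimnames = list(products, colnames(x@F)))
  new("CalibratedNetwork", Zbar = Zbar, Fbar = Fbar, a = a, b = b,
      xbar = as.numeric(x@x / stepsPerYear),
      vaBar = as.numeric(x@va / stepsPerYear), HD = HD,
      region = x@region, sector = x@sector,
      households = colnames(x@F), products = products,
      sectorIndex = as.integer(sectorIndex), stepsPerYear = stepsPerYear)
})

#' @rdname simConfig-class-helpers
#' @name simConfig
#' @title Simulation configuration and shock series constructors
#'
#' @description `simConfig()` sets the horizon, inventory cover target,
#' overproduction factor and the substitution exponent governing how clients
#' re-weight orders across suppliers by relative capacity.  `shockSeries()`
#' builds the exogenous shock object, optionally from a
#' \linkS4class{LabourAvailability} (columns are matched to firms by
#' region.sector name).
#'
#' @param horizon number of steps.
#' @param nTarget inventory target, steps of cover at current capacity.
#' @param overproduction capacity slack factor >= 1.
#' @param substitutionExponent exponent on relative supplier capacity in
#'   order reallocation (0 = fixed baseline shares).
#' @return `simConfig()`: a \linkS4class{SimConfig}.
#' @examples
#' simConfig(horizon = 120)
#' @export
simConfig <- function(horizon = 365, nTarget = 15, overproduction = 1,
                      substitutionExponent = 1) {
  new("SimConfig", horizon = horizon, nTarget = nTarget,
      overproduction = overproduction,
      substitutionExponent = substitutionExponent)
}

#' @rdname simConfig
#' @param network a \linkS4class{CalibratedNetwork}.
#' @param gammaL,gammaK steps x firms matrices of unavailable labour/capital
#'   shares in [0, 1]; scalars and vectors are recycled.  A
#'   \linkS4class{LabourAvailability} may be given as `gammaL`.
#' @param HD optional product x household x steps array of exogenous
#'   household demand (defaults to the calibrated baseline).
#' @export
shockSeries <- function(network, horizon, gammaL = 0, gammaK = 0, HD = NULL) {
  N <- length(network@xbar)
  expand <- function(g) {
    if (is(g, "LabourAvailability")) {
      firm <- paste(network@region, network@sector, sep = ".")
      idx <- match(firm, paste(g@region, g@sector, sep = "."))
      if (any(is.na(idx)))
        stop("labour availability lacks series for some firms")
      m <- g@gamma[, idx, drop = FALSE]
      if (nrow(m) < horizon)
        stop("labour availability shorter than the simulation horizon")
      return(m[seq_len(horizon), , drop = FALSE])
    }
    if (is.matrix(g)) {
      stopifnot(nrow(g) == horizon, ncol(g) == N)
      g
    } else matrix(g, horizon, N, byrow = length(g) == N)
  }
  if (is.null(HD)) HD <- array(numeric(0), dim = c(0, 0, 0))
  new("ShockSeries", gammaL = expand(gammaL), gammaK = expand(gammaK),
      HD = HD)
}

#' One simulation step of the adaptive input-output model
#'
#' Executes, in order: constrained production (labour, capital and
#' inventory capacity; actual output capped by last step's total orders),
#' inventory draw-down, order issuing against the post-use inventory
#' position, proportional allocation of output to the orders received last
#' step, and inventory restoration from receipts.  Orders are computed
#' before receipts arrive, which makes the no-shock trajectory an exact
#' fixed point of the dynamics.
#'
#' @param network a \linkS4class{CalibratedNetwork}.
#' @param state list with elements `S` (product x firm inventories), `FOD`
#'   (supplier x client orders), `HOD` (supplier x household orders), `TOD`
#'   (total orders received per supplier); see [initialState()].
#' @param gL,gK numeric per-firm unavailable shares at this step.
#' @param HDt product x household exogenous demand (baseline if NULL).
#' @param config a \linkS4class{SimConfig}.
#' @return Updated state list, with per-step `xa`, `xmax` attached.
#' @seealso [runFootprint()] which iterates this step and accumulates the
#'   footprint decomposition.
#' @export
stepFootprint <- function(network, state, gL, gK, HDt = NULL,
                          config = simConfig()) {
  A <- network@a; b <- network@b; xbar <- network@xbar
  sec <- network@sectorIndex
  if (is.null(HDt)) HDt <- network@HD

  ## production: capacity is the scarcest of labour, capital, inventories
  xL <- (1 - gL) * xbar
  xK <- (1 - gK) * xbar
  ratio <- state$S / A
  ratio[A == 0] <- Inf
  xP <- suppressWarnings(apply(ratio, 2L, min))   # Inf when no inputs used
  xmax <- pmin(xL, xK, xP) * config@overproduction
  xa <- pmin(xmax, state$TOD)
  if (any(!is.finite(xa)) || any(xa < 0))
    stop("non-finite or negative production encountered; state diverged")

  used <- A * rep(xa, each = nrow(A))
  Smid <- state$S - used                 # post-use inventory position
  Smid[Smid < 0] <- 0                    # guard against roundoff

  ## order issuing (before receipts arrive): inventory gap to target cover,
  ## split across suppliers by baseline share x relative capacity^psi
  psi <- config@substitutionExponent
  u <- ifelse(xbar > 0, xa / xbar, 0)^psi
  Sstar <- config@nTarget * A * rep(xmax, each = nrow(A))
  Sstar[A == 0] <- 0
  gap <- pmax(Sstar - Smid, 0)
  W <- network@Zbar * u                  # supplier rows scaled by capacity
  denom <- rowsum(W, sec)                # product x client totals
  denomBase <- rowsum(network@Zbar, sec)
  useBase <- denom <= 0 & denomBase > 0  # all candidate suppliers down
  Wb <- network@Zbar
  shares <- W / (denom[sec, , drop = FALSE])
  sharesBase <- Wb / (denomBase[sec, , drop = FALSE])
  shares[useBase[sec, , drop = FALSE]] <- sharesBase[useBase[sec, , drop = FALSE]]
  shares[!is.finite(shares)] <- 0
  FODnew <- gap[sec, , drop = FALSE] * shares

  Wh <- network@Fbar * u
  denomH <- rowsum(Wh, sec)
  denomHBase <- rowsum(network@Fbar, sec)
  useBaseH <- denomH <= 0 & denomHBase > 0
  sharesH <- Wh / (denomH[sec, , drop = FALSE])
  sharesHBase <- network@Fbar / (denomHBase[sec, , drop = FALSE])
  sharesH[useBaseH[sec, , drop = FALSE]] <- sharesHBase[useBaseH[sec, , drop = FALSE]]
  sharesH[!is.finite(sharesH)] <- 0
  HODnew <- HDt[sec, , drop = FALSE] * sharesH

  ## proportional rationing of this step's output against last step's orders
  tot <- rowSums(state$FOD) + rowSums(state$HOD)
  scaleAll <- ifelse(tot > 0, xa / tot, 0)
  FRC <- state$FOD * scaleAll
  HRC <- state$HOD * scaleAll

  ## receipts restore inventories by the supplier's product class
  restored <- rowsum(FRC, sec)
  Snew <- Smid + matrix(as.numeric(restored), nrow = nrow(A))

  firm <- colnames(A)
  dimnames(FODnew) <- dimnames(network@Zbar)
  dimnames(HODnew) <- dimnames(network@Fbar)
  dimnames(Snew) <- dimnames(A)
  list(S = Snew, FOD = FODnew, HOD = HODnew,
       TOD = setNames(rowSums(FODnew) + rowSums(HODnew), firm),
       xa = setNames(unname(xa), firm), xmax = setNames(unname(xmax), firm),
       FRC = FRC, HRC = HRC)
}

#' @rdname stepFootprint
#' @export
initialState <- function(network, config = simConfig()) {
  A <- network@a
  S0 <- config@nTarget * A * rep(network@xbar, each = nrow(A))
  list(S = S0, FOD = network@Zbar, HOD = network@Fbar,
       TOD = rowSums(network@Zbar) + rowSums(network@Fbar))
}

#' Run the adaptive input-output simulation and decompose losses
#'
#' Iterates [stepFootprint()] over the horizon under the exogenous shock
#' series and accumulates the footprint decomposition: per firm,
#' \eqn{TEF = \bar{va} T - \sum_t va^a(t)} (total),
#' \eqn{DEF = \bar{va} T - \sum_t va^{max}(t)} (direct, from the firm's own
#' capacity constraints, with \eqn{va^{max} = b\, x^{max}} capped at the
#' baseline) and \eqn{PEF = TEF - DEF} (propagated through the network).
#'
#' @param network a \linkS4class{CalibratedNetwork}.
#' @param shocks a \linkS4class{ShockSeries} (see [shockSeries()]).
#' @param config a \linkS4class{SimConfig}; its horizon must match the
#'   shock series.
#' @return A \linkS4class{FootprintResult}.
#' @examples
#' net <- calibrateNetwork(generateMRIO(mrioGenConfig(2, 2, seed = 5)),
#'                         stepsPerYear = 60)
#' sh <- shockSeries(net, 60, gammaL = 0)
#' sum(tef(runFootprint(net, sh, simConfig(horizon = 60))))  # 0 at no shock
#' @export
runFootprint <- function(network, shocks, config = simConfig()) {
  validObject(shocks)
  T <- config@horizon
  N <- length(network@xbar)
  if (nrow(shocks@gammaL) != T)
    stop("shock series length must equal the configured horizon")
  hasHD <- length(shocks@HD) > 0
  if (hasHD && dim(shocks@HD)[3] != T)
    stop("household demand series length must equal the horizon")

  state <- initialState(network, config)
  vaA <- matrix(0, T, N)
  vaMax <- matrix(0, T, N)
  for (t in seq_len(T)) {
    HDt <- if (hasHD) shocks@HD[, , t, drop = TRUE] else NULL
    if (hasHD && !is.matrix(HDt))
      HDt <- matrix(HDt, nrow = dim(shocks@HD)[1])
    state <- stepFootprint(network, state, shocks@gammaL[t, ],
                           shocks@gammaK[t, ], HDt, config)
    vaA[t, ] <- network@b * state$xa
    ## va^max is capped at baseline so DEF measures the shortfall the firm's
    ## own constraints impose, never a surplus from ample inventories
    vaMax[t, ] <- network@b * pmin(state$xmax, network@xbar)
  }
  tefv <- network@vaBar * T - colSums(vaA)
  defv <- network@vaBar * T - colSums(vaMax)
  firm <- paste(network@region, network@sector, sep = ".")
  colnames(vaA) <- colnames(vaMax) <- firm
  new("FootprintResult",
      tef = setNames(tefv, firm), def = setNames(defv, firm),
      pef = setNames(tefv - defv, firm),
      vaA = vaA, vaMax = vaMax, vaBar = network@vaBar,
      region = network@region, sector = network@sector, horizon = T)
}

#' Aggregate a footprint decomposition by region
#'
#' @param result a \linkS4class{FootprintResult}.
#' @return data.frame with per-region TEF, DEF, PEF (monetary units).
#' @importFrom stats setNames aggregate
#' @export
regionFootprint <- function(result) {
  df <- data.frame(region = result@region, tef = result@tef,
                   def = result@def, pef = result@pef)
  out <- aggregate(cbind(tef, def, pef) ~ region, df, sum)
  out[order(out$region), , drop = FALSE]
}
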