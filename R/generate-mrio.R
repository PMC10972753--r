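#' MRIOGenConfig: settings for the synthetic input-output table generator
#'
#' @slot nRegions,nSectors integer table dimensions (firms are
#'   region-sector pairs).
#' @slot flowDensity numeric in (0, 1], fraction of potential off-diagonal
#'   inter-firm flows that are nonzero (within-sector self-supply is always
#'   retained so balancing has full support).
#' @slot vaShareRange,finalShareRange numeric(2) in (0, 1), ranges of the
#'   per-firm value-added and final-demand shares of gross output.
#' @slot scale numeric, typical gross output per firm (monetary units/yr).
#' @slot sectorNames character, optional sector labels.
#' @slot seed integer RNG seed.
#' @export
setClass("MRIOGenConfig", representation(
  nRegions = "numeric", nSectors = "numeric", flowDensity = "numeric",
  vaShareRange = "numeric", finalShareRange = "numeric", scale = "numeric",
  sectorNames = "character", seed = "numeric"))

setValidity("MRIOGenConfig", function(object) {
  msg <- NULL
  if (object@nRegions < 1 || object@nSectors < 1)
    msg <- c(msg, "need at least one region and sector")
  if (object@flowDensity <= 0 || object@flowDensity > 1)
    msg <- c(msg, "flowDensity must lie in (0, 1]")
  rng <- function(r) length(r) == 2 && r[1] > 0 && r[2] < 1 && r[1] <= r[2]
  if (!rng(object@vaShareRange))
    msg <- c(msg, "vaShareRange must be an ordered pair inside (0, 1)")
  if (!rng(object@finalShareRange))
    msg <- c(msg, "finalShareRange must be an ordered pair inside (0, 1)")
  if (length(object@vaShareRange) == 2 && length(object@finalShareRange) == 2 &&
      object@vaShareRange[2] + object@finalShareRange[2] >= 1)
    msg <- c(msg, "vaShare + finalShare upper bounds must stay below 1 so intermediate flows remain positive")
  if (object@scale <= 0) msg <- c(msg, "scale must be > 0")
  if (is.null(msg)) TRUE else msg
})

.defaultSectorNames <- function(n) {
  canon <- c("services", "industry", "construction", "agriculture")
  if (n <= length(canon)) canon[seq_len(n)] else paste0("s", seq_len(n))
}

#' @rdname generateMRIO
#' @export
mrioGenConfig <- function(nRegions = 5, nSectors = 4, flowDensity = 0.7,
                          vaShareRange = c(0.25, 0.45),
                          finalShareRange = c(0.25, 0.45),
                          scale = 1000, sectorNames = character(),
                          seed = 1L) {
  new("MRIOGenConfig", nRegions = nRegions, nSectors = nSectors,
      flowDensity = flowDensity, vaShareRange = vaShareRange,
      finalShareRange = finalShareRange, scale = scale,
      sectorNames = sectorNames, seed = seed)
}

## Biproportional (RAS/IPF) scaling of a nonnegative matrix to prescribed
## row and column totals.  Requires sum(rowTarget) == sum(colTarget).
.ipfScale <- function(M, rowTarget, colTarget, tol = 1e-10, maxit = 10000L) {
  for (it in seq_len(maxit)) {
    rs <- rowSums(M)
    M <- M * ifelse(rs > 0, rowTarget / rs, 0)
    cs <- colSums(M)
    M <- sweep(M, 2L, ifelse(cs > 0, colTarget / cs, 0), "*")
    rres <- max(abs(rowSums(M) - rowTarget) / pmax(rowTarget, 1e-12))
    cres <- max(abs(colSums(M) - colTarget) / pmax(colTarget, 1e-12))
    if (max(rres, cres) < tol) return(M)
  }
  stop("iterative proportional fitting did not converge; ",
       "the sparsity pattern cannot support the prescribed totals")
}

#' Generate a balanced synthetic multiregional input-output table
#'
#' Gross outputs, value-added shares and final-demand shares are drawn at
#' random; intermediate flows start from a random support (with density
#' `flowDensity`, self-supply always kept) and are balanced to the implied
#' row/column totals by iterative proportional fitting, so both accounting
#' identities hold to a relative residual below 1e-8.  Final demand is split
#' across regional households with a home-region bias.
#'
#' @param config an \linkS4class{MRIOGenConfig} from `mrioGenConfig()`.
#' @return An \linkS4class{MRIOTable}.
#' @examples
#' mrio <- generateMRIO(mrioGenConfig(nRegions = 2, nSectors = 2, seed = 5))
#' max(abs(rowSums(flowMatrix(mrio)) + rowSums(finalDemand(mrio)) -
#'         grossOutput(mrio)))
#' @importFrom stats runif
#' @export
generateMRIO <- function(config) {
  validObject(config)
  R <- config@nRegions; S <- config@nSectors; N <- R * S
  secNames <- if (length(config@sectorNames)) config@sectorNames
              else .defaultSectorNames(S)
  stopifnot(length(secNames) == S)
  region <- rep(paste0("R", seq_len(R)), each = S)
  sector <- rep(secNames, R)
  firm <- paste(region, sector, sep = ".")

  out <- .withSeed(config@seed, {
    x <- config@scale * exp(rnorm(N, 0, 0.4))
    vaShare <- runif(N, config@vaShareRange[1], config@vaShareRange[2])
    va <- vaShare * x
    colTarget <- x - va

    fShare <- runif(N, config@finalShareRange[1], config@finalShareRange[2])
    fTot <- fShare * x
    fTot <- fTot * sum(va) / sum(fTot)   # global identity: sum(F) = sum(va)
    ## keep row totals for Z positive: cap final demand, redistribute excess
    for (k in 1:20) {
      cap <- 0.9 * x
      over <- fTot > cap
      if (!any(over)) break
      excess <- sum(fTot[over] - cap[over])
      fTot[over] <- cap[over]
      room <- cap - fTot
      fTot[!over] <- fTot[!over] + excess * room[!over] / sum(room[!over])
    }
    rowTarget <- x - fTot

    M <- matrix(runif(N * N, 0.5, 1.5), N, N)
    if (config@flowDensity < 1) {
      drop <- matrix(runif(N * N) > config@flowDensity, N, N)
      sameSector <- outer(sector, sector, "==")
      drop[sameSector] <- FALSE   # self-supply support always kept
      M[drop] <- 0
    }
    Z <- .ipfScale(M, rowTarget, colTarget)

    ## household split of final demand with home-region bias
    w <- matrix(runif(N * R, 0.5, 1.5), N, R)
    home <- outer(region, paste0("R", seq_len(R)), "==")
    w[home] <- w[home] * 3
    F <- fTot * w / rowSums(w)
    list(Z = Z, F = F, va = va, x = x)
  })

  dimnames(out$Z) <- list(firm, firm)
  dimnames(out$F) <- list(firm, paste0("R", seq_len(R)))
  names(out$va) <- names(out$x) <- firm
  new("MRIOTable", Z = out$Z, F = out$F, va = out$va, x = out$x,
      region = region, sector = sector)
}

#' Uniformly rescale an MRIO table's monetary units
#'
#' Multiplies every monetary entry (flows, final demand, value added, gross
#' output) by a common factor, preserving both balance identities exactly;
#' used to put a synthetic table on the same monetary footing as the
#' population's aggregate income.
#'
#' @param x an \linkS4class{MRIOTable}.
#' @param factor positive scalar.
#' @return The rescaled \linkS4class{MRIOTable}.
#' @export
scaleMRIO <- function(x, factor) {
  stopifnot(is(x, "MRIOTable"), factor > 0)
  new("MRIOTable", Z = x@Z * factor, F = x@F * factor,
      va = x@va * factor, x = x@x * factor,
      region = x@region, sector = x@sector)
}
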