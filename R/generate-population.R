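#' PopulationGenConfig: settings for the synthetic population generator
#'
#' @slot nLat,nLon integer grid dimensions (must match the climate grid they
#'   will be combined with).
#' @slot latRange,lonRange numeric(2) coordinate spans.
#' @slot totalPop numeric, world population (persons); cell populations sum
#'   to this exactly after largest-remainder rounding.
#' @slot clustering numeric >= 0, spatial concentration: 0 gives a
#'   near-uniform field, larger values concentrate people in fewer cells
#'   (cell weights are Gamma(1/clustering) draws).
#' @slot nRegions integer, number of regions; cells are partitioned into
#'   contiguous longitude bands labelled `R1..Rk`.
#' @slot mortality numeric, per-region baseline daily mortality rate
#'   (deaths per person-day); scalar recycled.
#' @slot income numeric, per-region income per capita (USD/yr); scalar
#'   recycled.
#' @slot seed integer RNG seed.
#' @export
setClass("PopulationGenConfig", representation(
  nLat = "numeric", nLon = "numeric", latRange = "numeric",
  lonRange = "numeric", totalPop = "numeric", clustering = "numeric",
  nRegions = "numeric", mortality = "numeric", income = "numeric",
  seed = "numeric"))

setValidity("PopulationGenConfig", function(object) {
  msg <- NULL
  if (object@totalPop < 0) msg <- c(msg, "totalPop must be >= 0")
  if (object@clustering < 0) msg <- c(msg, "clustering must be >= 0")
  if (object@nRegions < 1 || object@nRegions > object@nLon)
    msg <- c(msg, "need 1 <= nRegions <= nLon")
  if (any(object@mortality <= 0) || any(object@mortality >= 1))
    msg <- c(msg, "mortality rates must lie in (0, 1)")
  if (any(object@income <= 0)) msg <- c(msg, "incomes must be > 0")
  if (any(!is.finite(c(object@totalPop, object@clustering,
                       object@mortality, object@income))))
    msg <- c(msg, "settings must be finite")
  if (is.null(msg)) TRUE else msg
})

#' @rdname generatePopulation
#' @export
populationGenConfig <- function(nLat = 6, nLon = 10,
                                latRange = c(-55, 65), lonRange = c(0, 350),
                                totalPop = 1e8, clustering = 0.5,
                                nRegions = 5,
                                mortality = 2.4e-5, income = 15000,
                                seed = 1L) {
  new("PopulationGenConfig", nLat = nLat, nLon = nLon, latRange = latRange,
      lonRange = lonRange, totalPop = totalPop, clustering = clustering,
      nRegions = nRegions, mortality = rep_len(mortality, nRegions),
      income = rep_len(income, nRegions), seed = seed)
}

## Largest-remainder apportionment of `total` (integer) across weights.
.largestRemainder <- function(weights, total) {
  if (total == 0 || sum(weights) == 0) return(rep(0, length(weights)))
  quota <- weights / sum(weights) * total
  fl <- floor(quota)
  short <- round(total - sum(fl))
  if (short > 0) {
    idx <- order(quota - fl, decreasing = TRUE)[seq_len(short)]
    fl[idx] <- fl[idx] + 1
  }
  fl
}

#' Generate a synthetic population grid with region tables
#'
#' Cell populations are drawn as Gamma-distributed weights (shape
#' 1/clustering, so clustering -> 0 approaches a uniform field) apportioned
#' to the configured world total by the largest-remainder method, which makes
#' the total exact.  Cells are partitioned into `nRegions` contiguous
#' longitude bands labelled `R1..Rk`, each with a baseline daily mortality
#' rate and income per capita.
#'
#' @param config a \linkS4class{PopulationGenConfig} from
#'   `populationGenConfig()`.
#' @return A \linkS4class{PopulationGrid}.
#' @examples
#' pg <- generatePopulation(populationGenConfig(totalPop = 1e6, seed = 3))
#' sum(pg@pop) == 1e6
#' @importFrom stats rgamma
#' @export
generatePopulation <- function(config) {
  validObject(config)
  ccfg <- climateGenConfig(nLat = config@nLat, nLon = config@nLon,
                           latRange = config@latRange,
                           lonRange = config@lonRange)
  coords <- .gridCoords(ccfg)
  nc <- nrow(coords)
  w <- .withSeed(config@seed, {
    if (config@clustering == 0) rep(1, nc)
    else rgamma(nc, shape = 1 / config@clustering, rate = 1)
  })
  pop <- .largestRemainder(w, round(config@totalPop))

  band <- ceiling(match(coords$lon, sort(unique(coords$lon))) /
                    (config@nLon / config@nRegions))
  region <- paste0("R", pmin(band, config@nRegions))
  rt <- data.frame(region = paste0("R", seq_len(config@nRegions)),
                   mortality = config@mortality,
                   income = config@income)
  new("PopulationGrid", pop = as.numeric(pop), lat = coords$lat,
      lon = coords$lon, region = region, regionTable = rt)
}
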