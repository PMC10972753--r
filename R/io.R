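#' Read and write the package's plain-text interchange formats
#'
#' Grids are serialized as long-format CSV with explicit dimensional
#' columns (`year`, `doy`, `lat`, `lon`; variables `tmean`, `tmax`, `rh`),
#' a text rendering of the usual (time, lat, lon) gridded layout.  MRIO
#' tables are written as a directory of three CSVs: `flows.csv`
#' (origin_region, origin_sector, dest_region, dest_sector, flow),
#' `final_demand.csv` (origin_region, origin_sector, household, flow) and
#' `va.csv` (region, sector, va, x).  Labour availability is one row per
#' (region, sector, year, doy, gamma).  All writers round-trip through the
#' matching reader.
#'
#' @param x the object to write.
#' @param path a file (grids, gamma) or directory (MRIO) path.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @name heatfootprint-io
#' @importFrom utils read.csv write.csv
NULL

#' @rdname heatfootprint-io
#' @export
writeClimateGrid <- function(x, path) {
  stopifnot(is(x, "ClimateGrid"))
  cd <- colData(x); rd <- rowData(x)
  nd <- ncol(x); nc <- nrow(x)
  df <- data.frame(
    year = rep(cd$year, each = nc), doy = rep(cd$doy, each = nc),
    lat = rep(rd$lat, nd), lon = rep(rd$lon, nd),
    tmean = as.numeric(tmean(x)), tmax = as.numeric(tmax(x)),
    rh = as.numeric(relHumidity(x)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname heatfootprint-io
#' @export
readClimateGrid <- function(path) {
  df <- read.csv(path)
  cells <- unique(df[, c("lat", "lon")])
  days <- unique(df[, c("year", "doy")])
  nc <- nrow(cells); nd <- nrow(days)
  shape <- function(v) matrix(v, nc, nd)
  se <- SummarizedExperiment(
    assays = list(tmean = shape(df$tmean), tmax = shape(df$tmax),
                  rh = shape(df$rh)),
    rowData = DataFrame(lat = cells$lat, lon = cells$lon,
                        row.names = sprintf("cell%04d", seq_len(nc))),
    colData = DataFrame(year = days$year, doy = days$doy))
  new("ClimateGrid", se)
}

#' @rdname heatfootprint-io
#' @export
writeMRIO <- function(x, path) {
  stopifnot(is(x, "MRIOTable"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  N <- length(x@x)
  flows <- data.frame(
    origin_region = rep(x@region, N), origin_sector = rep(x@sector, N),
    dest_region = rep(x@region, each = N),
    dest_sector = rep(x@sector, each = N),
    flow = as.numeric(x@Z))
  write.csv(flows, file.path(path, "flows.csv"), row.names = FALSE)
  fd <- data.frame(
    origin_region = rep(x@region, ncol(x@F)),
    origin_sector = rep(x@sector, ncol(x@F)),
    household = rep(colnames(x@F), each = N),
    flow = as.numeric(x@F))
  write.csv(fd, file.path(path, "final_demand.csv"), row.names = FALSE)
  va <- data.frame(region = x@region, sector = x@sector,
                   va = as.numeric(x@va), x = as.numeric(x@x))
  write.csv(va, file.path(path, "va.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname heatfootprint-io
#' @export
readMRIO <- function(path) {
  va <- read.csv(file.path(path, "va.csv"))
  firm <- paste(va$region, va$sector, sep = ".")
  N <- nrow(va)
  flows <- read.csv(file.path(path, "flows.csv"))
  Z <- matrix(0, N, N, dimnames = list(firm, firm))
  oi <- match(paste(flows$origin_region, flows$origin_sector, sep = "."), firm)
  di <- match(paste(flows$dest_region, flows$dest_sector, sep = "."), firm)
  Z[cbind(oi, di)] <- flows$flow
  fd <- read.csv(file.path(path, "final_demand.csv"))
  households <- sort(unique(fd$household))
  F <- matrix(0, N, length(households), dimnames = list(firm, households))
  F[cbind(match(paste(fd$origin_region, fd$origin_sector, sep = "."), firm),
          match(fd$household, households))] <- fd$flow
  new("MRIOTable", Z = Z, F = F,
      va = setNames(va$va, firm), x = setNames(va$x, firm),
      region = va$region, sector = va$sector)
}

#' @rdname heatfootprint-io
#' @export
writeGamma <- function(x, path) {
  stopifnot(is(x, "LabourAvailability"))
  nT <- nrow(x@gamma); nF <- ncol(x@gamma)
  df <- data.frame(
    region = rep(x@region, each = nT), sector = rep(x@sector, each = nT),
    year = rep(x@year, nF), doy = rep(x@doy, nF),
    gamma = as.numeric(x@gamma))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname heatfootprint-io
#' @export
readGamma <- function(path) {
  df <- read.csv(path)
  key <- paste(df$region, df$sector, sep = ".")
  firms <- unique(key)
  first <- key == firms[1]
  gamma <- matrix(df$gamma, ncol = length(firms))
  colnames(gamma) <- firms
  new("LabourAvailability", gamma = gamma,
      year = as.integer(df$year[first]), doy = as.integer(df$doy[first]),
      region = df$region[match(firms, key)],
      sector = df$sector[match(firms, key)])
}

#' Serialize a climate generator config to and from YAML
#'
#' @param config a \linkS4class{ClimateGenConfig}.
#' @param path YAML file path.
#' @return `readClimateConfig()` returns the reconstructed config.
#' @export
writeClimateConfig <- function(config, path) {
  sl <- slotNames(config)
  lst <- lapply(setNames(sl, sl), function(s) slot(config, s))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeClimateConfig
#' @export
readClimateConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(climateGenConfig, lst[names(lst) %in% names(formals(climateGenConfig))])
}

#' @rdname heatfootprint-io
#' @export
readRRTable <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("zone", "rr") %in% names(df)))
  if (any(df$rr < 1)) stop("relative risks must be >= 1")
  setNames(df$rr, as.character(df$zone))
}

#' @rdname heatfootprint-io
#' @export
readIntensityMap <- function(path) {
  lst <- yaml::read_yaml(path)
  lapply(lst, function(e)
    workIntensity(level = e$level, setting = e$setting,
                  prodMean = e$prodMean, prodSD = e$prodSD,
                  alpha1 = e$alpha1, alpha2 = e$alpha2))
}
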