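#' @include AllClasses.R
NULL

#' Accessors for heatfootprint classes
#'
#' Small accessor generics: \code{tmean}, \code{tmax}, \code{relHumidity}
#' return the climate assays of a \linkS4class{ClimateGrid}; \code{wbgtMean},
#' \code{wbgtMax}, \code{wbgtHalf} the exposure assays of a
#' \linkS4class{WBGTGrid}; \code{hwn} and \code{eventMask} the annual
#' heatwave-day counts and daily mask of a \linkS4class{HeatwaveStats};
#' \code{flowMatrix}, \code{finalDemand}, \code{valueAdded},
#' \code{grossOutput} the blocks of an \linkS4class{MRIOTable};
#' \code{tef}, \code{def}, \code{pef} the footprints of a
#' \linkS4class{FootprintResult}; \code{regions} and \code{sectors} the
#' firm labels of economic objects.
#'
#' @param x an object of the documented class.
#' @return The matrix, vector or character labels stored in the
#'   corresponding slot or assay.
#' @name accessors
#' @aliases tmean tmax relHumidity wbgtMean wbgtMax wbgtHalf hwn eventMask
#'   flowMatrix finalDemand valueAdded grossOutput tef def pef regions
#'   sectors gammaSeries
NULL

#' @rdname accessors
#' @export
setGeneric("tmean", function(x) standardGeneric("tmean"))
#' @rdname accessors
#' @export
setGeneric("tmax", function(x) standardGeneric("tmax"))
#' @rdname accessors
#' @export
setGeneric("relHumidity", function(x) standardGeneric("relHumidity"))
#' @rdname accessors
#' @export
setGeneric("wbgtMean", function(x) standardGeneric("wbgtMean"))
#' @rdname accessors
#' @export
setGeneric("wbgtMax", function(x) standardGeneric("wbgtMax"))
#' @rdname accessors
#' @export
setGeneric("wbgtHalf", function(x) standardGeneric("wbgtHalf"))
#' @rdname accessors
#' @export
setGeneric("hwn", function(x) standardGeneric("hwn"))
#' @rdname accessors
#' @export
setGeneric("eventMask", function(x) standardGeneric("eventMask"))
#' @rdname accessors
#' @export
setGeneric("flowMatrix", function(x) standardGeneric("flowMatrix"))
#' @rdname accessors
#' @export
setGeneric("finalDemand", function(x) standardGeneric("finalDemand"))
#' @rdname accessors
#' @export
setGeneric("valueAdded", function(x) standardGeneric("valueAdded"))
#' @rdname accessors
#' @export
setGeneric("grossOutput", function(x) standardGeneric("grossOutput"))
#' @rdname accessors
#' @export
setGeneric("tef", function(x) standardGeneric("tef"))
#' @rdname accessors
#' @export
setGeneric("def", function(x) standardGeneric("def"))
#' @rdname accessors
#' @export
setGeneric("pef", function(x) standardGeneric("pef"))
#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @rdname accessors
#' @export
setGeneric("sectors", function(x) standardGeneric("sectors"))
#' @rdname accessors
#' @export
setGeneric("gammaSeries", function(x) standardGeneric("gammaSeries"))

#' @describeIn computeWBGT generic
#' @export
setGeneric("computeWBGT", function(x, ...) standardGeneric("computeWBGT"))

#' @describeIn detectHeatwaves generic
#' @export
setGeneric("detectHeatwaves", function(x, ...) standardGeneric("detectHeatwaves"))

#' @describeIn calibrateNetwork generic
#' @export
setGeneric("calibrateNetwork", function(x, ...) standardGeneric("calibrateNetwork"))

## ---- accessor methods -----------------------------------------------------

#' @rdname accessors
#' @export
setMethod("tmean", "ClimateGrid", function(x) assay(x, "tmean"))
#' @rdname accessors
#' @export
setMethod("tmax", "ClimateGrid", function(x) assay(x, "tmax"))
#' @rdname accessors
#' @export
setMethod("relHumidity", "ClimateGrid", function(x) assay(x, "rh"))
#' @rdname accessors
#' @export
setMethod("wbgtMean", "WBGTGrid", function(x) assay(x, "wbgtMean"))
#' @rdname accessors
#' @export
setMethod("wbgtMax", "WBGTGrid", function(x) assay(x, "wbgtMax"))
#' @rdname accessors
#' @export
setMethod("wbgtHalf", "WBGTGrid", function(x) assay(x, "wbgtHalf"))
#' @rdname accessors
#' @export
setMethod("hwn", "HeatwaveStats", function(x) x@hwn)
#' @rdname accessors
#' @export
setMethod("eventMask", "HeatwaveStats", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("flowMatrix", "MRIOTable", function(x) x@Z)
#' @rdname accessors
#' @export
setMethod("finalDemand", "MRIOTable", function(x) x@F)
#' @rdname accessors
#' @export
setMethod("valueAdded", "MRIOTable", function(x) x@va)
#' @rdname accessors
#' @export
setMethod("grossOutput", "MRIOTable", function(x) x@x)
#' @rdname accessors
#' @export
setMethod("regions", "MRIOTable", function(x) x@region)
#' @rdname accessors
#' @export
setMethod("sectors", "MRIOTable", function(x) x@sector)
#' @rdname accessors
#' @export
setMethod("regions", "CalibratedNetwork", function(x) x@region)
#' @rdname accessors
#' @export
setMethod("sectors", "CalibratedNetwork", function(x) x@sector)
#' @rdname accessors
#' @export
setMethod("tef", "FootprintResult", function(x) x@tef)
#' @rdname accessors
#' @export
setMethod("def", "FootprintResult", function(x) x@def)
#' @rdname accessors
#' @export
setMethod("pef", "FootprintResult", function(x) x@pef)
#' @rdname accessors
#' @export
setMethod("regions", "FootprintResult", function(x) x@region)
#' @rdname accessors
#' @export
setMethod("sectors", "FootprintResult", function(x) x@sector)
#' @rdname accessors
#' @export
setMethod("gammaSeries", "LabourAvailability", function(x) x@gamma)

## ---- show methods ---------------------------------------------------------

setMethod("show", "MRIOTable", function(object) {
  cat(sprintf("MRIOTable: %d firms (%d regions x %d sectors), %d households\n",
              length(object@x), length(unique(object@region)),
              length(unique(object@sector)), ncol(object@F)))
  cat(sprintf("  gross output total: %.4g; balance residual: %.2e\n",
              sum(object@x),
              .mrioResiduals(object@Z, object@F, object@va, object@x)))
})

setMethod("show", "HeatwaveStats", function(object) {
  cat(sprintf("HeatwaveStats: %d cells x %d days (%d years)\n",
              nrow(object@mask), ncol(object@mask), ncol(object@hwn)))
  cat(sprintf("  definition: >%.4g%% threshold, >=%d-day runs%s\n",
              object@definition@percentile, as.integer(object@definition@minRun),
              if (object@definition@dynamic) ", dynamic" else ""))
  cat(sprintf("  mean annual HWN: %.2f days\n", mean(object@hwn)))
})

setMethod("show", "FootprintResult", function(object) {
  cat(sprintf("FootprintResult: %d firms, horizon %d steps\n",
              length(object@tef), as.integer(object@horizon)))
  cat(sprintf("  TEF = %.6g  DEF = %.6g  PEF = %.6g (world totals)\n",
              sum(object@tef), sum(object@def), sum(object@pef)))
})

setMethod("show", "LabourAvailability", function(object) {
  cat(sprintf("LabourAvailability: %d days x %d region-sector series\n",
              nrow(object@gamma), ncol(object@gamma)))
  cat(sprintf("  mean gamma on active days: %.4f\n",
              mean(object@gamma[object@gamma > 0])))
})

setMethod("show", "CalibratedNetwork", function(object) {
  cat(sprintf("CalibratedNetwork: %d firms, %d products, %d households; %d steps/yr\n",
              length(object@xbar), length(object@products),
              length(object@households), as.integer(object@stepsPerYear)))
})
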