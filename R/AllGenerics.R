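#' Accessors for fibreSR classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nFibres", function(x) standardGeneric("nFibres"))

#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("fovCenter", function(x) standardGeneric("fovCenter"))

#' @rdname accessors
#' @export
setGeneric("fovRadius", function(x) standardGeneric("fovRadius"))

#' @rdname accessors
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname accessors
#' @export
setGeneric("cellSizes", function(x) standardGeneric("cellSizes"))

#' @rdname accessors
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("paddedLength", function(x) standardGeneric("paddedLength"))

#' @rdname accessors
#' @export
setGeneric("fibreIds", function(x) standardGeneric("fibreIds"))

#' @rdname accessors
#' @export
setGeneric("frameData", function(x) standardGeneric("frameData"))

#' @rdname accessors
#' @export
setGeneric("frameRole", function(x) standardGeneric("frameRole"))

#' @rdname accessors
#' @export
setGeneric("lossTerms", function(x) standardGeneric("lossTerms"))

#' @rdname accessors
#' @export
setGeneric("reportRows", function(x) standardGeneric("reportRows"))

#' @rdname accessors
#' @export
setGeneric("reportAggregates", function(x) standardGeneric("reportAggregates"))

#' @rdname accessors
setMethod("nFibres", "FibreLayout", function(x) nrow(x@positions))
#' @rdname accessors
setMethod("nFibres", "FibreSignalVector", function(x) x@nFibres)
#' @rdname accessors
setMethod("nFibres", "VoronoiMap", function(x) length(x@cellSizes))
#' @rdname accessors
setMethod("positions", "FibreLayout", function(x) x@positions)
#' @rdname accessors
setMethod("fovCenter", "FibreLayout", function(x) x@fovCenter)
#' @rdname accessors
setMethod("fovRadius", "FibreLayout", function(x) x@fovRadius)
#' @rdname accessors
setMethod("cellLabels", "VoronoiMap", function(x) x@labels)
#' @rdname accessors
setMethod("cellSizes", "VoronoiMap", function(x) x@cellSizes)
#' @rdname accessors
setMethod("signalValues", "FibreSignalVector", function(x) x@values)
#' @rdname accessors
setMethod("isNormalized", "FibreSignalVector", function(x) x@normalized)
#' @rdname accessors
setMethod("paddedLength", "FibreSignalVector", function(x) x@paddedLength)
#' @rdname accessors
setMethod("fibreIds", "FibreSignalVector", function(x) x@fibreIds)
#' @rdname accessors
setMethod("frameData", "ImageFrame", function(x) x@data)
#' @rdname accessors
setMethod("frameRole", "ImageFrame", function(x) x@role)
#' @rdname accessors
setMethod("lossTerms", "LossBreakdown", function(x)
  c(l_vec = x@lVec, l_adv = x@lAdv, l_reg = x@lReg, total = x@total))
#' @rdname accessors
setMethod("reportRows", "MetricsReport", function(x) x@rows)
#' @rdname accessors
setMethod("reportAggregates", "MetricsReport", function(x) x@aggregates)

setMethod("show", "ImageFrame", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageFrame [%s] %d x %d, range [%.4g, %.4g]\n",
              if (nzchar(object@role)) object@role else "untagged",
              d[1], d[2], min(object@data), max(object@data)))
})

setMethod("show", "FibreLayout", function(object) {
  cat(sprintf("FibreLayout: %d fibres, FOV centre (%.1f, %.1f), radius %.1f px\n",
              nrow(object@positions), object@fovCenter[1], object@fovCenter[2],
              object@fovRadius))
})

setMethod("show", "VoronoiMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("VoronoiMap: %d x %d grid, %d fibres, %d in-FOV pixels\n",
              d[1], d[2], length(object@cellSizes), sum(object@cellSizes)))
})

setMethod("show", "FibreSignalVector", function(object) {
  cat(sprintf("FibreSignalVector: %d fibres, padded to %d, %s\n",
              object@nFibres, object@paddedLength,
              if (object@normalized) "normalized [0,1]" else "raw"))
})

setMethod("show", "LossBreakdown", function(object) {
  cat(sprintf("LossBreakdown: l_vec %.5g | l_adv %.5g | l_reg %.5g | total %.5g\n",
              object@lVec, object@lAdv, object@lReg, object@total))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (%s): %d images\n",
              if (nzchar(object@caseStudy)) object@caseStudy else "untagged",
              nrow(object@rows)))
  ag <- object@aggregates
  for (i in seq_len(nrow(ag)))
    cat(sprintf("  %-8s %.2f ± %.2f\n", ag$metric[i], ag$mean[i], ag$sd[i]))
})
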