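#' @include AllClasses.R
NULL

#' Accessors for the package's S4 classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("roiPixels", function(x) standardGeneric("roiPixels"))
#' @rdname accessors
#' @export
setMethod("roiPixels", "ThyroidROI", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("roiBox", function(x) standardGeneric("roiBox"))
#' @rdname accessors
#' @export
setMethod("roiBox", "ThyroidROI", function(x) x@box)
#' @rdname accessors
#' @export
setMethod("roiBox", "PhantomSample", function(x) x@truthROI)

#' @rdname accessors
#' @export
setGeneric("scoreValue", function(x) standardGeneric("scoreValue"))
#' @rdname accessors
#' @export
setMethod("scoreValue", "FrequencyScore", function(x) x@value)
#' @rdname accessors
#' @export
setMethod("scoreValue", "FusedScore", function(x) x@value)
#' @rdname accessors
#' @export
setMethod("scoreValue", "ClassScore", function(x) x@pBenign)

#' @rdname accessors
#' @param which for \code{boxRange}: \code{"row"} or \code{"col"}.
#' @export
boxRange <- function(x, which = c("row", "col")) {
  stopifnot(is(x, "BoundingBox"))
  which <- match.arg(which)
  if (which == "row") c(x@rowStart, x@rowEnd) else c(x@colStart, x@colEnd)
}

#' @rdname accessors
#' @export
setGeneric("thresholdBounds", function(x) standardGeneric("thresholdBounds"))
#' @rdname accessors
#' @export
setMethod("thresholdBounds", "CoarseThresholds",
          function(x) c(low = x@thLow, high = x@thHigh))

#' @rdname accessors
#' @export
setGeneric("resultLabel", function(x) standardGeneric("resultLabel"))
#' @rdname accessors
#' @export
setMethod("resultLabel", "CascadeResult", function(x) x@label)
#' @rdname accessors
#' @export
setGeneric("resultPath", function(x) standardGeneric("resultPath"))
#' @rdname accessors
#' @export
setMethod("resultPath", "CascadeResult", function(x) x@path)

#' @rdname accessors
#' @export
setGeneric("reportMetrics", function(x) standardGeneric("reportMetrics"))
#' @rdname accessors
#' @export
setMethod("reportMetrics", "EvalReport", function(x)
  c(sensitivity = x@sensitivity, specificity = x@specificity,
    accuracy = x@accuracy))

#' @rdname accessors
#' @export
setGeneric("reportCounts", function(x) standardGeneric("reportCounts"))
#' @rdname accessors
#' @export
setMethod("reportCounts", "EvalReport", function(x)
  c(tp = x@counts@tp, fn = x@counts@fn, tn = x@counts@tn, fp = x@counts@fp))

#' @rdname accessors
#' @export
setGeneric("manifestSamples", function(x) standardGeneric("manifestSamples"))
#' @rdname accessors
#' @export
setMethod("manifestSamples", "Manifest", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("lossLog", function(x) standardGeneric("lossLog"))
#' @rdname accessors
#' @export
setMethod("lossLog", "CNNModel", function(x) x@lossLog)

#' @rdname accessors
#' @export
setGeneric("modelLayers", function(x) standardGeneric("modelLayers"))
#' @rdname accessors
#' @export
setMethod("modelLayers", "CNNModel", function(x) x@layers)

#' @rdname accessors
#' @export
setGeneric("phantomImage", function(x) standardGeneric("phantomImage"))
#' @rdname accessors
#' @export
setMethod("phantomImage", "PhantomSample", function(x) x@image)

#' @rdname accessors
#' @export
setGeneric("phantomLabel", function(x) standardGeneric("phantomLabel"))
#' @rdname accessors
#' @export
setMethod("phantomLabel", "PhantomSample", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("foldAssignments", function(x) standardGeneric("foldAssignments"))
#' @rdname accessors
#' @export
setMethod("foldAssignments", "FoldSplit", function(x) x@assignments)

#' @rdname accessors
#' @export
setGeneric("coarseThresholds", function(x) standardGeneric("coarseThresholds"))
#' @rdname accessors
#' @export
setMethod("coarseThresholds", "CascadeModel", function(x) x@thresholds)

#' @rdname accessors
#' @export
setGeneric("cascadeModels", function(x) standardGeneric("cascadeModels"))
#' @rdname accessors
#' @export
setMethod("cascadeModels", "CascadeModel", function(x) x@models)

#' @rdname accessors
#' @export
setGeneric("decisionThreshold", function(x)
  standardGeneric("decisionThreshold"))
#' @rdname accessors
#' @export
setMethod("decisionThreshold", "CascadeModel",
          function(x) x@decisionThreshold)
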