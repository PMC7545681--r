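#' @rdname ClusterCensus-class
#' @param object,x a morphome object.
#' @param ... passed to methods.
#' @export
setGeneric("clusters", function(x, ...) standardGeneric("clusters"))

#' @rdname ClusterCensus-class
#' @export
setGeneric("excludedClusters",
           function(x, ...) standardGeneric("excludedClusters"))

#' @rdname ClusterCensus-class
#' @export
setGeneric("maxSize", function(x, ...) standardGeneric("maxSize"))

#' @rdname MorphomeExperiment-class
#' @export
setGeneric("morphomeMatrix", function(x, ...) standardGeneric("morphomeMatrix"))

#' @rdname MorphomeExperiment-class
#' @export
setGeneric("survivalOutcome", function(x, ...) standardGeneric("survivalOutcome"))

#' @rdname StabilityReport-class
#' @export
setGeneric("selectedFeatures",
           function(x, ...) standardGeneric("selectedFeatures"))

#' @rdname StabilityReport-class
#' @export
setGeneric("selectionFrequency",
           function(x, ...) standardGeneric("selectionFrequency"))

#' @rdname CoxnetCV-class
#' @export
setGeneric("lambdaOpt", function(x, ...) standardGeneric("lambdaOpt"))

#' @rdname CoxPHFit-class
#' @export
setGeneric("hazardRatios", function(x, ...) standardGeneric("hazardRatios"))

#' @rdname KMEstimate-class
#' @export
setGeneric("medianSurvival", function(x, ...) standardGeneric("medianSurvival"))
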