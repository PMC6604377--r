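#' @rdname normCounts
#' @export
setGeneric("normCounts", function(object) standardGeneric("normCounts"))

#' @rdname groupFactor
#' @export
setGeneric("groupFactor", function(object) standardGeneric("groupFactor"))

#' @rdname covariateMatrix
#' @export
setGeneric("covariateMatrix",
           function(object) standardGeneric("covariateMatrix"))

#' @rdname ziExpFit
#' @export
setGeneric("ziExpFit", function(object, ...) standardGeneric("ziExpFit"))

#' @rdname ziExpLRT
#' @export
setGeneric("ziExpLRT", function(object, ...) standardGeneric("ziExpLRT"))

#' @rdname filterLowInfo
#' @export
setGeneric("filterLowInfo",
           function(object, ...) standardGeneric("filterLowInfo"))

#' @rdname yanTwoStepFilter
#' @export
setGeneric("yanTwoStepFilter",
           function(object, ...) standardGeneric("yanTwoStepFilter"))

#' @rdname cvProfile
#' @export
setGeneric("cvProfile", function(object, ...) standardGeneric("cvProfile"))

#' @rdname simulateCounts
#' @export
setGeneric("simulateCounts",
           function(object, ...) standardGeneric("simulateCounts"))

#' @rdname ZIExpFit-accessors
#' @export
setGeneric("piEstimates", function(object) standardGeneric("piEstimates"))

#' @rdname ZIExpFit-accessors
#' @export
setGeneric("groupMeans", function(object) standardGeneric("groupMeans"))

#' @rdname ZIExpFit-accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname ZIExpFit-accessors
#' @export
setGeneric("logLiks", function(object) standardGeneric("logLiks"))

#' @rdname fittedMeans
#' @export
setGeneric("fittedMeans", function(object, ...) standardGeneric("fittedMeans"))
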