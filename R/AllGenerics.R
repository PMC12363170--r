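#' @rdname AbundanceTable-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname AbundanceTable-class
#' @export
setGeneric("tableKind", function(x) standardGeneric("tableKind"))

#' @rdname AbundanceTable-class
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname AbundanceTable-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname CorrelationResult-class
#' @export
setGeneric("corMatrix", function(x) standardGeneric("corMatrix"))

#' @rdname CorrelationResult-class
#' @export
setGeneric("basisVariances", function(x) standardGeneric("basisVariances"))

#' @rdname CorrelationResult-class
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname CorrelationResult-class
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))

#' @rdname CoNetwork-class
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname CoNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname CoNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname ModulePartition-class
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname ModulePartition-class
#' @export
setGeneric("majorLabels", function(x) standardGeneric("majorLabels"))

#' @rdname ModulePartition-class
#' @export
setGeneric("modularityQ", function(x) standardGeneric("modularityQ"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("plantedModules", function(x) standardGeneric("plantedModules"))
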