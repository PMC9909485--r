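#' @rdname TissueAssociation-class
#' @param object,x A result object.
#' @export
setGeneric("assocTable", function(x) standardGeneric("assocTable"))

#' @rdname TissueAssociation-class
#' @export
setGeneric("passingGenes", function(x) standardGeneric("passingGenes"))

#' @rdname TissueAssociation-class
#' @export
setGeneric("passingTissues", function(x) standardGeneric("passingTissues"))

#' @rdname CoexpressionModules-class
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname CoexpressionModules-class
#' @export
setGeneric("moduleEigengenes", function(x) standardGeneric("moduleEigengenes"))

#' @rdname CoexpressionModules-class
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))

#' @rdname MINetwork-class
#' @export
setGeneric("miEdges", function(x) standardGeneric("miEdges"))

#' @rdname MINetwork-class
#' @export
setGeneric("componentSizes", function(x) standardGeneric("componentSizes"))

#' @rdname SimTruth-class
#' @export
setGeneric("truthMarkers", function(x) standardGeneric("truthMarkers"))

#' @rdname SimTruth-class
#' @export
setGeneric("truthModules", function(x) standardGeneric("truthModules"))
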