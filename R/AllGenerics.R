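#' @rdname ExpressionMatrix-class
#' @param object,x an object.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("cellNames", function(x) standardGeneric("cellNames"))

#' @rdname ExpressionMatrix-class
#' @param value replacement value.
#' @export
setGeneric("cellNames<-", function(x, value) standardGeneric("cellNames<-"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("exprState", function(x) standardGeneric("exprState"))

#' @rdname PathwayCollection-class
#' @export
setGeneric("pathways", function(x) standardGeneric("pathways"))

#' @rdname PathwayCollection-class
#' @export
setGeneric("nPathways", function(x) standardGeneric("nPathways"))

#' @rdname GeneGrouping-class
#' @export
setGeneric("groupIds", function(x) standardGeneric("groupIds"))

#' @rdname GeneGrouping-class
#' @export
setGeneric("groupSource", function(x) standardGeneric("groupSource"))

#' @rdname GeneGrouping-class
#' @export
setGeneric("groupGenes", function(x) standardGeneric("groupGenes"))

#' @rdname GeneGrouping-class
#' @export
setGeneric("tokensPerProfile", function(x) standardGeneric("tokensPerProfile"))

#' @rdname PredictionSet-class
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))

#' @rdname AlignmentModel-class
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))

#' @rdname AlignmentModel-class
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname AlignmentModel-class
#' @export
setGeneric("modelGrouping", function(x) standardGeneric("modelGrouping"))
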