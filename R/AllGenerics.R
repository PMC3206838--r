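#' @rdname ExpressionStudy-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("studyId", function(x) standardGeneric("studyId"))

#' @rdname ExpressionStudy-class
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname ExpressionStudy-class
#' @export
setGeneric("phenoTable", function(x) standardGeneric("phenoTable"))

#' @rdname SubspaceModel-class
#' @export
setGeneric("loadings", function(x) standardGeneric("loadings"))

#' @rdname SubspaceModel-class
#' @export
setGeneric("metagenes", function(x) standardGeneric("metagenes"))

#' @rdname SubspaceModel-class
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname DecomposedExpression-class
#' @export
setGeneric("projectedPart", function(x) standardGeneric("projectedPart"))

#' @rdname DecomposedExpression-class
#' @export
setGeneric("residualPart", function(x) standardGeneric("residualPart"))

#' @rdname IRResult-class
#' @export
setGeneric("irValue", function(x) standardGeneric("irValue"))

#' @rdname IRResult-class
#' @export
setGeneric("typeLabel", function(x) standardGeneric("typeLabel"))

#' @rdname WeightModel-class
#' @export
setGeneric("geneWeights", function(x) standardGeneric("geneWeights"))

#' @rdname AccuracyResult-class
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
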