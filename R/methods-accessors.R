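#' @rdname ExpressionStudy-class
#' @aliases studyId,ExpressionStudy-method
setMethod("studyId", "ExpressionStudy", function(x) x@studyId)

#' @rdname ExpressionStudy-class
#' @aliases exprMatrix,ExpressionStudy-method
setMethod("exprMatrix", "ExpressionStudy",
          function(x) SummarizedExperiment::assay(x, "log2expr"))

#' @rdname ExpressionStudy-class
#' @aliases phenoTable,ExpressionStudy-method
setMethod("phenoTable", "ExpressionStudy", function(x) {
  df <- as.data.frame(SummarizedExperiment::colData(x))
  df
})

#' @rdname SubspaceModel-class
#' @aliases loadings,SubspaceModel-method
setMethod("loadings", "SubspaceModel", function(x) x@loadings)

#' @rdname SubspaceModel-class
#' @aliases metagenes,SubspaceModel-method
setMethod("metagenes", "SubspaceModel", function(x) x@metagenes)

#' @rdname SubspaceModel-class
#' @aliases eigenvalues,SubspaceModel-method
setMethod("eigenvalues", "SubspaceModel", function(x) x@eigenvalues)

#' @rdname DecomposedExpression-class
#' @aliases projectedPart,DecomposedExpression-method
setMethod("projectedPart", "DecomposedExpression", function(x) x@projected)

#' @rdname DecomposedExpression-class
#' @aliases residualPart,DecomposedExpression-method
setMethod("residualPart", "DecomposedExpression", function(x) x@residual)

#' @rdname IRResult-class
#' @aliases irValue,IRResult-method
setMethod("irValue", "IRResult", function(x) x@ir)

#' @rdname IRResult-class
#' @aliases typeLabel,IRResult-method
setMethod("typeLabel", "IRResult", function(x) x@typeLabel)

#' @rdname WeightModel-class
#' @aliases geneWeights,WeightModel-method
setMethod("geneWeights", "WeightModel", function(x) x@weights)

#' @rdname AccuracyResult-class
#' @aliases accuracy,AccuracyResult-method
setMethod("accuracy", "AccuracyResult", function(x) x@accuracy)

#' @rdname ExpressionStudy-class
setMethod("show", "ExpressionStudy", function(object) {
  cat(sprintf("ExpressionStudy '%s': %d genes x %d samples\n",
              object@studyId, nrow(object), ncol(object)))
  pv <- setdiff(colnames(SummarizedExperiment::colData(object)), character())
  cat(sprintf("phenotype variables (%d): %s\n", length(pv),
              if (length(pv)) paste(utils::head(pv, 8L), collapse = ", ")
              else "<none>"))
})

#' @rdname SubspaceModel-class
setMethod("show", "SubspaceModel", function(object) {
  cat(sprintf("SubspaceModel: n = %d over %d genes, %d samples\n",
              object@nDim, nrow(object@loadings), ncol(object@metagenes)))
  cat("eigenvalues:", paste(signif(object@eigenvalues, 4L), collapse = ", "),
      "\n")
  if (length(object@droppedGenes))
    cat(sprintf("%d constant gene(s) dropped from the fit\n",
                length(object@droppedGenes)))
})

#' @rdname DecomposedExpression-class
setMethod("show", "DecomposedExpression", function(object) {
  cat(sprintf("DecomposedExpression: %d genes x %d samples (n = %d)\n",
              nrow(object@projected), ncol(object@projected),
              ncol(object@coefficients)))
})

#' @rdname DifferentialResult-class
setMethod("show", "DifferentialResult", function(object) {
  cat(sprintf("DifferentialResult '%s' (%s): %d genes\n",
              object@contrastName, object@method, length(object@geneIds)))
  cat(sprintf("min p: original %.3g, projected %.3g, residual %.3g\n",
              min(object@pOriginal), min(object@pProjected),
              min(object@pResidual)))
})

#' @rdname WeightModel-class
setMethod("show", "WeightModel", function(object) {
  cat(sprintf("WeightModel: lambda = %.4g over %d bins, %d genes\n",
              object@lambda, object@nBins, length(object@weights)))
})

#' @rdname IRResult-class
setMethod("show", "IRResult", function(object) {
  cat(sprintf("IRResult '%s': IR = %.4f (n = %d, lambda = %.3g, %d genes) [%s]\n",
              object@contrastName, object@ir, object@nDim, object@lambda,
              object@nGenesUsed, object@typeLabel))
})

#' @rdname BinaryContrast-class
setMethod("show", "BinaryContrast", function(object) {
  tab <- table(object@labels)
  cat(sprintf("BinaryContrast '%s': class1 n = %d, class2 n = %d\n",
              object@name, tab[["class1"]], tab[["class2"]]))
})

#' @rdname RankedGeneList-class
setMethod("show", "RankedGeneList", function(object) {
  cat(sprintf("RankedGeneList (%s / %s): top %.1f%%, %d genes\n",
              object@sourceStudy, object@contrastName,
              100 * object@fraction, length(object@geneIds)))
})

#' @rdname AccuracyResult-class
setMethod("show", "AccuracyResult", function(object) {
  cat(sprintf("AccuracyResult (%s / %s): accuracy = %.3f over %d outer folds\n",
              object@studyId, object@contrastName, object@accuracy,
              length(object@foldAccuracies)))
})

#' @rdname TransferResult-class
setMethod("show", "TransferResult", function(object) {
  cat(sprintf(
    "TransferResult %s -> %s (%s): source %.3f, target %.3f, loss %.3f\n",
    object@sourceStudy, object@targetStudy, object@contrastName,
    object@sourceAccuracy, object@targetAccuracy, object@loss))
})

#' @rdname SimConfig-class
setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d genes x %d samples, dim = %d, mode = %s, effect = %.2g, seed = %d\n",
    object@nGenes, object@nSamples, object@dim, object@signalMode,
    object@effectSize, object@seed))
})
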