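#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
NULL

#' ExpressionStudy: a log2 expression matrix with per-sample phenotypes
#'
#' Container for one expression study: a genes x samples matrix of
#' log2-scale expression values plus a per-sample phenotype table. Extends
#' \linkS4class{SummarizedExperiment}; the expression matrix is the assay
#' named \code{"log2expr"} and the phenotype table is the \code{colData}.
#'
#' Invariants enforced by the validity method: gene and sample identifiers
#' are unique, every expression value is finite, and \code{studyId} is a
#' single string.
#'
#' @slot studyId single character label identifying the study.
#' @seealso \code{\link{ExpressionStudy}} (constructor),
#'   \code{\link{loadExpression}}
#' @export
setClass("ExpressionStudy",
  contains = "SummarizedExperiment",
  representation(studyId = "character")
)

setValidity("ExpressionStudy", function(object) {
  msg <- character()
  if (length(object@studyId) != 1L || is.na(object@studyId))
    msg <- c(msg, "studyId must be a single non-NA string")
  gid <- rownames(object)
  sid <- colnames(object)
  if (is.null(gid) || is.null(sid))
    msg <- c(msg, "gene and sample identifiers (dimnames) are required")
  if (!is.null(gid) && anyDuplicated(gid))
    msg <- c(msg, sprintf("duplicated gene identifiers: %s",
      paste(unique(gid[duplicated(gid)])[1:min(3, sum(duplicated(gid)))], collapse = ", ")))
  if (!is.null(sid) && anyDuplicated(sid))
    msg <- c(msg, sprintf("duplicated sample identifiers: %s",
      paste(unique(sid[duplicated(sid)])[1:min(3, sum(duplicated(sid)))], collapse = ", ")))
  if (length(SummarizedExperiment::assays(object)) >= 1L) {
    a <- SummarizedExperiment::assay(object, 1L)
    if (!all(is.finite(a))) {
      bad <- which(!apply(is.finite(a), 1L, all))
      msg <- c(msg, sprintf("non-finite expression values in gene(s): %s",
        paste(utils::head(rownames(a)[bad], 3L), collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' ContrastSpec: a rule pair that binarizes one phenotype variable
#'
#' Describes how a phenotype column is turned into a two-class contrast:
#' a named variable plus one rule per class. A rule is either a value set
#' (categorical) or a numeric interval. Samples matching neither rule, or
#' with a missing value, are excluded from the contrast.
#'
#' @slot name contrast name.
#' @slot variable phenotype column the rules apply to.
#' @slot class1Rule,class2Rule rule lists built by \code{\link{setRule}} or
#'   \code{\link{rangeRule}}.
#' @slot excludeIfTrue optional phenotype column; samples where it is true
#'   are excluded (used e.g. to drop patients censored before five years in
#'   relapse contrasts). \code{NA_character_} to disable.
#' @seealso \code{\link{contrastSpec}}, \code{\link{builtinContrasts}},
#'   \code{\link{binarizePhenotype}}
#' @export
setClass("ContrastSpec",
  representation(
    name = "character",
    variable = "character",
    class1Rule = "list",
    class2Rule = "list",
    excludeIfTrue = "character"
  )
)

setValidity("ContrastSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (length(object@variable) != 1L) msg <- c(msg, "variable must be a single string")
  for (r in list(object@class1Rule, object@class2Rule)) {
    if (is.null(r$type) || !r$type %in% c("set", "range"))
      msg <- c(msg, "rules must have type 'set' or 'range'")
  }
  r1 <- object@class1Rule; r2 <- object@class2Rule
  if (identical(r1$type, "set") && identical(r2$type, "set") &&
      length(intersect(as.character(r1$values), as.character(r2$values))))
    msg <- c(msg, "class1 and class2 value sets overlap")
  if (identical(r1$type, "range") && identical(r2$type, "range")) {
    if (.rangesOverlap(r1, r2))
      msg <- c(msg, "class1 and class2 intervals overlap")
  }
  if (length(msg)) msg else TRUE
})

#' BinaryContrast: a two-class sample partition
#'
#' The realized contrast on a concrete study: the retained samples and
#' their class labels. Both classes must contain at least two samples.
#'
#' @slot name contrast name.
#' @slot sampleIds retained sample identifiers, in study order.
#' @slot labels factor with levels \code{class1}, \code{class2}.
#' @export
setClass("BinaryContrast",
  representation(name = "character", sampleIds = "character", labels = "factor")
)

setValidity("BinaryContrast", function(object) {
  msg <- character()
  if (length(object@sampleIds) != length(object@labels))
    msg <- c(msg, "sampleIds and labels differ in length")
  if (!identical(levels(object@labels), c("class1", "class2")))
    msg <- c(msg, "labels must be a factor with levels class1, class2")
  tab <- table(object@labels)
  if (any(tab < 2L))
    msg <- c(msg, sprintf("class '%s' has fewer than 2 samples",
                          names(tab)[which(tab < 2L)[1L]]))
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "duplicated sample identifiers in contrast")
  if (length(msg)) msg else TRUE
})

#' SubspaceModel: leading eigenvectors of the gene-gene correlation matrix
#'
#' The fitted n-dimensional subspace: gene loadings (eigenvectors of the
#' gene-gene Pearson correlation matrix of the log2 expression), the
#' derived metagene expression profiles across samples, the eigenvalues,
#' and the per-gene means/sds used for standardization. Loadings columns
#' are orthonormal; eigenvalues are sorted decreasing.
#'
#' @slot nDim subspace dimension n.
#' @slot loadings genes x n matrix of eigenvector gene loadings (rows
#'   restricted to genes with positive variance).
#' @slot metagenes n x samples matrix of metagene expression profiles (the
#'   loadings-weighted sums of the standardized gene rows).
#' @slot eigenvalues length-n decreasing, non-negative.
#' @slot geneMeans,geneSds named per-gene statistics over samples (all
#'   genes of the study, including any dropped constant genes).
#' @slot droppedGenes genes excluded from the fit because their sd is 0.
#' @seealso \code{\link{fitSubspace}}, \code{\link{splitExpression}}
#' @export
setClass("SubspaceModel",
  representation(
    nDim = "integer",
    loadings = "matrix",
    metagenes = "matrix",
    eigenvalues = "numeric",
    geneMeans = "numeric",
    geneSds = "numeric",
    droppedGenes = "character"
  )
)

setValidity("SubspaceModel", function(object) {
  msg <- character()
  n <- object@nDim
  if (ncol(object@loadings) != n) msg <- c(msg, "loadings must have nDim columns")
  if (nrow(object@metagenes) != n) msg <- c(msg, "metagenes must have nDim rows")
  if (length(object@eigenvalues) != n) msg <- c(msg, "eigenvalues must have length nDim")
  if (any(diff(object@eigenvalues) > 1e-10))
    msg <- c(msg, "eigenvalues must be sorted decreasing")
  if (any(object@eigenvalues < -1e-10))
    msg <- c(msg, "eigenvalues must be non-negative")
  g <- crossprod(object@loadings)
  if (max(abs(g - diag(n))) > 1e-8)
    msg <- c(msg, "loadings columns must be orthonormal")
  if (length(msg)) msg else TRUE
})

#' DecomposedExpression: per-gene split into projected and residual parts
#'
#' For every gene the expression row is split as x = x_p + x_r, where x_p
#' is the least-squares projection of the centered row onto the span of
#' the metagene profiles and x_r carries the remainder (including the gene
#' mean). The centered residual row is orthogonal to every centered
#' metagene profile.
#'
#' @slot projected,residual genes x samples matrices (x_p and x_r).
#' @slot coefficients genes x n matrix of per-gene projection coefficients.
#' @seealso \code{\link{splitExpression}}
#' @export
setClass("DecomposedExpression",
  representation(projected = "matrix", residual = "matrix",
                 coefficients = "matrix")
)

setValidity("DecomposedExpression", function(object) {
  msg <- character()
  if (!identical(dim(object@projected), dim(object@residual)))
    msg <- c(msg, "projected and residual must share dimensions")
  if (nrow(object@coefficients) != nrow(object@projected))
    msg <- c(msg, "coefficients must have one row per gene")
  if (length(msg)) msg else TRUE
})

#' DifferentialResult: per-gene p-values in original, projected and
#' residual space
#'
#' Differential-expression p-values for one binary contrast, computed
#' gene-wise by Welch's t-test (or Wilcoxon rank-sum) on the original
#' expression, the projected component x_p, and the residual component
#' x_r. p-values are clamped to [pFloor, 1]; lp fields are their log10.
#'
#' @slot geneIds ordered gene identifiers.
#' @slot pOriginal,pProjected,pResidual per-gene p-values in (0, 1].
#' @slot lpOriginal,lpProjected,lpResidual log10 p-values (<= 0).
#' @slot method \code{"welch_t"} or \code{"wilcoxon"}.
#' @slot contrastName the contrast the result belongs to.
#' @seealso \code{\link{differentialAllSpaces}}
#' @export
setClass("DifferentialResult",
  representation(
    geneIds = "character",
    pOriginal = "numeric", pProjected = "numeric", pResidual = "numeric",
    lpOriginal = "numeric", lpProjected = "numeric", lpResidual = "numeric",
    method = "character", contrastName = "character"
  )
)

setValidity("DifferentialResult", function(object) {
  msg <- character()
  n <- length(object@geneIds)
  lens <- c(length(object@pOriginal), length(object@pProjected),
            length(object@pResidual), length(object@lpOriginal),
            length(object@lpProjected), length(object@lpResidual))
  if (any(lens != n)) msg <- c(msg, "all p/lp vectors must match geneIds length")
  for (p in list(object@pOriginal, object@pProjected, object@pResidual))
    if (length(p) && (any(p <= 0) || any(p > 1)))
      msg <- c(msg, "p-values must lie in (0, 1]")
  if (length(object@lpOriginal) && any(object@lpOriginal > 1e-12))
    msg <- c(msg, "lp values must be <= 0")
  if (length(msg)) msg else TRUE
})

#' WeightModel: exponential gene-weight distribution fitted from log10
#' p-values
#'
#' The genome-wide |log10 p| values are collected into equidistant bins;
#' the per-bin occupancy ratios follow, for most phenotypes, an
#' exponential decay, whose rate lambda is estimated by log-linear
#' regression over the occupied bins. Per-gene weights are
#' w_i = exp(lambda * |log10 p_i|), so that gene groups of similar
#' sensitivity contribute equally in weighted sums.
#'
#' @slot lambda decay rate per unit |log10 p| (>= 0).
#' @slot nBins number of equidistant bins (default 50).
#' @slot binEdges length nBins + 1, spanning [0, max|lp|].
#' @slot binRatios per-bin occupancy ratios, summing to 1.
#' @slot weights named per-gene weights.
#' @seealso \code{\link{fitLambda}}, \code{\link{informationRatio}}
#' @export
setClass("WeightModel",
  representation(lambda = "numeric", nBins = "integer",
                 binEdges = "numeric", binRatios = "numeric",
                 weights = "numeric")
)

setValidity("WeightModel", function(object) {
  msg <- character()
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (length(object@binEdges) != object@nBins + 1L)
    msg <- c(msg, "binEdges must have nBins + 1 entries")
  if (abs(sum(object@binRatios) - 1) > 1e-12)
    msg <- c(msg, "binRatios must sum to 1")
  if (any(object@weights < 1 - 1e-12))
    msg <- c(msg, "weights must be >= 1 (exp of a non-negative quantity)")
  if (length(msg)) msg else TRUE
})

#' IRResult: the Information Ratio for one study/contrast
#'
#' The Information Ratio is the weighted mean over genes of
#' |lp_r| / (|lp_r| + |lp_p|): 0 when the phenotype information is fully
#' captured by the leading PCA subspace, 1 when it resides entirely in the
#' residual space. Contrasts with IR at or below the threshold (default
#' 0.25) are classified as low ("type1_low"), all others as high
#' ("type2_3_high").
#'
#' @slot ir the Information Ratio in [0, 1].
#' @slot lambda the fitted weight-decay rate.
#' @slot nDim the subspace dimension used.
#' @slot nGenesUsed number of genes entering the weighted sum.
#' @slot typeLabel \code{"type1_low"} or \code{"type2_3_high"}.
#' @slot contrastName contrast the IR belongs to.
#' @seealso \code{\link{informationRatio}}, \code{\link{irForContrast}}
#' @export
setClass("IRResult",
  representation(ir = "numeric", lambda = "numeric", nDim = "integer",
                 nGenesUsed = "integer", typeLabel = "character",
                 contrastName = "character")
)

setValidity("IRResult", function(object) {
  msg <- character()
  if (object@ir < 0 || object@ir > 1) msg <- c(msg, "ir must lie in [0, 1]")
  if (!object@typeLabel %in% c("type1_low", "type2_3_high"))
    msg <- c(msg, "typeLabel must be type1_low or type2_3_high")
  if (length(msg)) msg else TRUE
})

#' RankedGeneList: the top fraction of genes ranked by p-value
#'
#' Genes ordered by increasing original-space Welch p-value (ties broken
#' by gene identifier); the list is the head of length
#' max(1, floor(fraction * n_genes)).
#'
#' @slot geneIds the ranked head.
#' @slot fraction fraction of the gene universe retained (default 0.05).
#' @slot sourceStudy,contrastName provenance labels.
#' @seealso \code{\link{topGeneList}}, \code{\link{pog}}
#' @export
setClass("RankedGeneList",
  representation(geneIds = "character", fraction = "numeric",
                 sourceStudy = "character", contrastName = "character")
)

#' AccuracyResult: nested cross-validated SVM accuracy
#'
#' Mean held-out accuracy of an RBF-kernel SVM under nested stratified
#' cross-validation: the outer loop selects the top genes by Welch p-value
#' within each training split and measures accuracy on the untouched test
#' fold; the inner loop tunes cost and gamma.
#'
#' @slot studyId,contrastName provenance labels.
#' @slot accuracy mean over outer folds.
#' @slot foldAccuracies per-outer-fold accuracies.
#' @slot selectedGenes per-fold selected gene lists.
#' @slot tunedParams per-fold tuned (cost, gamma) pairs.
#' @slot seed RNG seed used for fold assignment.
#' @seealso \code{\link{intraStudyAccuracy}}
#' @export
setClass("AccuracyResult",
  representation(studyId = "character", contrastName = "character",
                 accuracy = "numeric", foldAccuracies = "numeric",
                 selectedGenes = "list", tunedParams = "matrix",
                 seed = "integer")
)

setValidity("AccuracyResult", function(object) {
  msg <- character()
  if (abs(object@accuracy - mean(object@foldAccuracies)) > 1e-12)
    msg <- c(msg, "accuracy must equal the mean of foldAccuracies")
  if (any(object@foldAccuracies < 0 | object@foldAccuracies > 1))
    msg <- c(msg, "fold accuracies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' TransferResult: accuracy loss when a gene list crosses studies
#'
#' A gene list ranked on the source study's full data is used to train
#' default-parameter SVM classifiers in both source and target study
#' (10-fold cross-validation each); the loss is source minus target
#' accuracy.
#'
#' @slot sourceStudy,targetStudy,contrastName provenance labels.
#' @slot sourceAccuracy,targetAccuracy,loss accuracies and their
#'   difference.
#' @seealso \code{\link{transferAccuracy}}
#' @export
setClass("TransferResult",
  representation(sourceStudy = "character", targetStudy = "character",
                 contrastName = "character", sourceAccuracy = "numeric",
                 targetAccuracy = "numeric", loss = "numeric")
)

setValidity("TransferResult", function(object) {
  if (abs(object@loss -
          (object@sourceAccuracy - object@targetAccuracy)) > 1e-12)
    "loss must equal sourceAccuracy - targetAccuracy" else TRUE
})

#' SimConfig: parameters of the latent-factor expression simulator
#'
#' Configuration of one synthetic study: a low-rank latent-factor
#' component (dim factors, loadings with unit-variance columns, factor
#' scores scaled by factorSd) plus independent per-gene Gaussian noise,
#' with a binary phenotype whose differential signal is placed either
#' inside the leading-factor subspace or orthogonal to it.
#'
#' @slot nGenes,nSamples matrix dimensions (defaults 2000 x 100).
#' @slot dim intrinsic dimensionality d, 1-100.
#' @slot noiseSd,factorSd noise and factor-score standard deviations
#'   (defaults 1 and 3).
#' @slot signalMode \code{"subspace"} or \code{"residual"}.
#' @slot effectSize class-2 mean shift, in units of noiseSd (default 2).
#' @slot nSignalGenes number of genes carrying the shift (default 100).
#' @slot balance class-1 fraction (default 0.5).
#' @slot signalFactors in subspace mode, how many leading factors the
#'   phenotype loads on (default 1).
#' @slot seed integer RNG seed.
#' @seealso \code{\link{simConfig}}, \code{\link{simulateStudy}}
#' @export
setClass("SimConfig",
  representation(nGenes = "integer", nSamples = "integer", dim = "integer",
                 noiseSd = "numeric", factorSd = "numeric",
                 signalMode = "character", effectSize = "numeric",
                 nSignalGenes = "integer", balance = "numeric",
                 signalFactors = "integer", seed = "integer")
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@dim < 1L || object@dim > 100L)
    msg <- c(msg, "dim must lie in 1..100")
  if (object@dim > min(object@nGenes, object@nSamples) - 1L)
    msg <- c(msg, "dim must be <= min(nGenes, nSamples) - 1")
  if (object@nSignalGenes > object@nGenes)
    msg <- c(msg, "nSignalGenes must be <= nGenes")
  if (!object@signalMode %in% c("subspace", "residual"))
    msg <- c(msg, "signalMode must be 'subspace' or 'residual'")
  if (object@noiseSd <= 0 || object@factorSd <= 0)
    msg <- c(msg, "noiseSd and factorSd must be > 0")
  if (object@balance <= 0 || object@balance >= 1)
    msg <- c(msg, "balance must lie strictly between 0 and 1")
  if (object@signalFactors < 1L || object@signalFactors > object@dim)
    msg <- c(msg, "signalFactors must lie in 1..dim")
  if (length(msg)) msg else TRUE
})

# interval overlap helper shared with contrast construction
.rangesOverlap <- function(r1, r2) {
  lo <- max(r1$min, r2$min)
  hi <- min(r1$max, r2$max)
  if (lo < hi) return(TRUE)
  if (lo > hi) return(FALSE)
  # touching endpoints: overlap only if the common point is inside both
  inside1 <- if (lo == r1$min) isTRUE(r1$includeMin) else isTRUE(r1$includeMax)
  inside2 <- if (lo == r2$min) isTRUE(r2$includeMin) else isTRUE(r2$includeMax)
  inside1 && inside2
}
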