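#' @importFrom e1071 svm
NULL

# stratified fold assignment: within each class, shuffle and deal out
# fold ids round-robin; caller controls the RNG state
.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in levels(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.svmFit <- function(x, y, cost, gamma) {
  suppressWarnings(e1071::svm(x = x, y = y, kernel = "radial",
                              cost = cost, gamma = gamma))
}

.svmAccuracy <- function(fit, x, y) {
  mean(predict(fit, x) == y)
}

#' Nested cross-validated SVM accuracy within one study
#'
#' Estimates the achievable accuracy of an RBF-kernel SVM for a binary
#' contrast, with univariate gene selection, under nested stratified
#' cross-validation. The outer loop (default 10-fold) selects, inside
#' each training split, the top-\code{fraction} genes by Welch p-value
#' -- selection never sees the test fold -- and measures accuracy on the
#' untouched test fold; the inner loop (default 10-fold) grid-searches
#' the SVM cost and gamma. When the minority class is smaller than the
#' requested fold count, the fold count is reduced to the minority size
#' (with a notice). The whole procedure is deterministic given
#' \code{seed}.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param contrast a \linkS4class{BinaryContrast} (or spec/name).
#' @param fraction gene-selection fraction, default 0.05.
#' @param seed integer seed controlling fold assignment.
#' @param nOuterFolds,nInnerFolds fold counts, default 10 and 10.
#' @param costGrid,gammaGrid tuning grids for the RBF-SVM; defaults
#'   cost in 2^(-2, 0, 2, 4, 6) and gamma in 2^(-8, -6, -4, -2, 0, 2).
#' @return An \linkS4class{AccuracyResult}.
#' @export
intraStudyAccuracy <- function(study, contrast, fraction = 0.05, seed = 1L,
                               nOuterFolds = 10L, nInnerFolds = 10L,
                               costGrid = 2^seq(-2, 6, by = 2),
                               gammaGrid = 2^seq(-8, 2, by = 2)) {
  stopifnot(is(study, "ExpressionStudy"))
  if (!is(contrast, "BinaryContrast"))
    contrast <- binarizePhenotype(study, contrast)
  x <- exprMatrix(study)[, contrast@sampleIds, drop = FALSE]
  y <- contrast@labels
  minority <- min(table(y))
  if (minority < 2L) stop("a class is too small for any split")
  kOut <- min(nOuterFolds, minority)
  if (kOut < nOuterFolds)
    message("outer fold count reduced to minority class size (", kOut, ")")
  set.seed(as.integer(seed))
  folds <- .stratifiedFolds(y, kOut)
  len <- max(1L, floor(fraction * nrow(x)))
  foldAcc <- numeric(kOut)
  selected <- vector("list", kOut)
  tuned <- matrix(NA_real_, kOut, 2L, dimnames = list(NULL, c("cost", "gamma")))
  for (f in seq_len(kOut)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    p <- rowWelchP(x[, tr, drop = FALSE],
                   which(y[tr] == "class1"), which(y[tr] == "class2"))
    sel <- rownames(x)[order(p, rownames(x))][seq_len(len)]
    xtr <- t(x[sel, tr, drop = FALSE])
    ytr <- y[tr]
    kIn <- min(nInnerFolds, min(table(ytr)))
    inner <- .stratifiedFolds(ytr, kIn)
    grid <- expand.grid(cost = costGrid, gamma = gammaGrid,
                        KEEP.OUT.ATTRS = FALSE)
    gridAcc <- vapply(seq_len(nrow(grid)), function(i) {
      mean(vapply(seq_len(kIn), function(g) {
        itr <- inner != g
        fit <- .svmFit(xtr[itr, , drop = FALSE], ytr[itr],
                       grid$cost[i], grid$gamma[i])
        .svmAccuracy(fit, xtr[!itr, , drop = FALSE], ytr[!itr])
      }, numeric(1L)))
    }, numeric(1L))
    # ties in the grid search resolve toward the libSVM default
    # parameterization (cost 1, gamma 1/n_features)
    cand <- which(gridAcc >= max(gridAcc) - 1e-12)
    dist <- log2(grid$cost[cand])^2 +
      (log2(grid$gamma[cand]) - log2(1 / length(sel)))^2
    pick <- cand[which.min(dist)]
    fit <- .svmFit(xtr, ytr, grid$cost[pick], grid$gamma[pick])
    foldAcc[f] <- .svmAccuracy(fit, t(x[sel, te, drop = FALSE]), y[te])
    selected[[f]] <- sel
    tuned[f, ] <- c(grid$cost[pick], grid$gamma[pick])
  }
  new("AccuracyResult", studyId = studyId(study),
      contrastName = contrast@name, accuracy = mean(foldAcc),
      foldAccuracies = foldAcc, selectedGenes = selected,
      tunedParams = tuned, seed = as.integer(seed))
}

# plain k-fold CV accuracy of a default-parameter RBF-SVM on a fixed
# gene list
.cvAccuracyFixedGenes <- function(study, contrast, genes, nFolds = 10L) {
  x <- exprMatrix(study)[genes, contrast@sampleIds, drop = FALSE]
  y <- contrast@labels
  k <- min(nFolds, min(table(y)))
  folds <- .stratifiedFolds(y, k)
  accs <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    fit <- .svmFit(t(x[, tr, drop = FALSE]), y[tr],
                   cost = 1, gamma = 1 / length(genes))
    .svmAccuracy(fit, t(x[, !tr, drop = FALSE]), y[!tr])
  }, numeric(1L))
  mean(accs)
}

#' Accuracy loss when a gene list is transferred between studies
#'
#' Ranks genes on the source study's full data (Welch p-value, original
#' space), takes the top fraction, and evaluates a default-parameter
#' RBF-SVM (cost 1, gamma 1/n_genes) restricted to that list by
#' stratified 10-fold cross-validation within each study. The source
#' accuracy is deliberately optimistic -- the list was selected on all
#' source data -- which is exactly the bias incurred when a published
#' signature is reused; the loss is source minus target accuracy.
#'
#' @param source,target \linkS4class{ExpressionStudy} objects sharing one
#'   gene set.
#' @param contrast a \linkS4class{ContrastSpec} or contrast name,
#'   binarized in each study.
#' @param fraction gene-list fraction, default 0.05.
#' @param seed integer seed controlling fold assignment.
#' @param nFolds CV folds, default 10.
#' @return A \linkS4class{TransferResult}.
#' @export
transferAccuracy <- function(source, target, contrast, fraction = 0.05,
                             seed = 1L, nFolds = 10L) {
  stopifnot(is(source, "ExpressionStudy"), is(target, "ExpressionStudy"))
  if (!identical(rownames(source), rownames(target)))
    stop("source and target must share one gene universe; run intersectGenes() first")
  if (is.character(contrast)) contrast <- builtinContrasts(contrast)
  cSrc <- binarizePhenotype(source, contrast)
  cTgt <- binarizePhenotype(target, contrast)
  x <- exprMatrix(source)[, cSrc@sampleIds, drop = FALSE]
  p <- rowWelchP(x, which(cSrc@labels == "class1"),
                 which(cSrc@labels == "class2"))
  len <- max(1L, floor(fraction * nrow(x)))
  genes <- rownames(x)[order(p, rownames(x))][seq_len(len)]
  set.seed(as.integer(seed))
  accSrc <- .cvAccuracyFixedGenes(source, cSrc, genes, nFolds)
  accTgt <- .cvAccuracyFixedGenes(target, cTgt, genes, nFolds)
  new("TransferResult", sourceStudy = studyId(source),
      targetStudy = studyId(target), contrastName = cSrc@name,
      sourceAccuracy = accSrc, targetAccuracy = accTgt,
      loss = accSrc - accTgt)
}

#' Relate the Information Ratio to achievable classifier accuracy
#'
#' For every (study, contrast) cell: computes the IR and the nested
#' cross-validated SVM accuracy, then summarises the cells by the IR
#' threshold -- mean accuracy of the low-IR group versus the high-IR
#' group, a Welch two-sample t-test for the difference, and the Pearson
#' correlation between IR and accuracy.
#'
#' @param studies list of \linkS4class{ExpressionStudy} objects.
#' @param contrastSpecs contrast name(s) or \linkS4class{ContrastSpec}
#'   object(s).
#' @param n subspace dimension, default 4.
#' @param fraction gene-selection fraction, default 0.05.
#' @param seed integer seed for the accuracy estimates.
#' @param irThreshold group boundary, default 0.25.
#' @return A list with \code{table} (one row per cell: study, contrast,
#'   ir, accuracy), \code{meanAccuracyLowIR}, \code{meanAccuracyHighIR},
#'   \code{welchP} (NA with a notice when a group is empty), and
#'   \code{pearsonR} (NA when undefined).
#' @export
irVsAccuracyReport <- function(studies, contrastSpecs, n = 4,
                               fraction = 0.05, seed = 1L,
                               irThreshold = 0.25) {
  if (is(studies, "ExpressionStudy")) studies <- list(studies)
  if (!is.list(contrastSpecs) || is(contrastSpecs, "ContrastSpec"))
    contrastSpecs <- list(contrastSpecs)
  rows <- list()
  for (study in studies) {
    for (cs in contrastSpecs) {
      spec <- if (is.character(cs)) builtinContrasts(cs) else cs
      contrast <- tryCatch(binarizePhenotype(study, spec),
                           error = function(e) NULL)
      if (is.null(contrast)) next
      irRes <- irForContrast(study, contrast, n = n)
      acc <- intraStudyAccuracy(study, contrast, fraction = fraction,
                                seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        study = studyId(study), contrast = contrast@name,
        ir = irValue(irRes), accuracy = accuracy(acc),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) < 2L) stop("need at least 2 (study, contrast) cells")
  tab <- do.call(rbind, rows)
  low <- tab$accuracy[tab$ir <= irThreshold]
  high <- tab$accuracy[tab$ir > irThreshold]
  wp <- NA_real_
  if (length(low) >= 2L && length(high) >= 2L) {
    if (stats::sd(c(low, high)) == 0) {
      wp <- 1
    } else {
      wp <- tryCatch(stats::t.test(low, high)$p.value,
                     error = function(e) NA_real_)
    }
  } else {
    message("a group is empty or too small; Welch test skipped")
  }
  pr <- if (nrow(tab) >= 3L && stats::sd(tab$ir) > 0 &&
            stats::sd(tab$accuracy) > 0)
    stats::cor(tab$ir, tab$accuracy) else NA_real_
  list(table = tab,
       meanAccuracyLowIR = if (length(low)) mean(low) else NA_real_,
       meanAccuracyHighIR = if (length(high)) mean(high) else NA_real_,
       welchP = wp, pearsonR = pr)
}
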