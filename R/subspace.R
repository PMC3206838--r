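#' Fit the leading PCA subspace of the gene-gene correlation structure
#'
#' Computes the top-n eigenpairs of the gene-gene Pearson correlation
#' matrix of the log2 expression and the derived metagene expression
#' profiles. The eigenvector k is a vector of gene loadings; its metagene
#' profile across samples is the loadings-weighted sum of the
#' standardized gene rows. The space spanned by the first n metagene
#' profiles is S_n; everything orthogonal to it (within sample space) is
#' the residual space S_r.
#'
#' Rather than forming the n_genes x n_genes correlation matrix, the
#' eigenpairs are obtained from the singular value decomposition of the
#' row-standardized expression matrix (each gene centered and scaled to
#' unit sd); eigenvalue k equals s_k^2 / (n_samples - 1) for singular
#' value s_k. Genes with zero variance cannot be standardized and are
#' dropped from the fit with a warning. The sign of each loading column
#' is fixed so that its largest-magnitude entry is positive; downstream
#' projection results are invariant to any rotation of the loading
#' columns, so only the spanned subspace matters.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param n subspace dimension, default 4; must satisfy
#'   1 <= n <= min(n_genes, n_samples - 1).
#' @return A \linkS4class{SubspaceModel}.
#' @examples
#' sim <- simulateStudy(simConfig(nGenes = 200, nSamples = 40, seed = 1))
#' fitSubspace(sim$study, n = 4)
#' @export
fitSubspace <- function(study, n = 4) {
  stopifnot(is(study, "ExpressionStudy"))
  n <- as.integer(n)
  x <- exprMatrix(study)
  m <- ncol(x)
  mu <- rowMeans(x)
  sds <- apply(x, 1L, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all genes are constant; cannot fit a subspace")
  if (!all(keep))
    warning(sum(!keep), " constant gene(s) dropped from the subspace fit")
  if (n < 1L || n > min(sum(keep), m - 1L))
    stop("n must lie in 1..min(n_genes, n_samples - 1) = ",
         min(sum(keep), m - 1L))
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sds[keep]
  sv <- svd(z, nu = n, nv = 0L)
  ev <- sv$d[seq_len(n)]^2 / (m - 1L)
  g <- sv$u
  # sign convention: largest-magnitude entry of each loading column positive
  flip <- vapply(seq_len(n), function(k) {
    i <- which.max(abs(g[, k]))
    if (g[i, k] < 0) -1 else 1
  }, numeric(1L))
  g <- sweep(g, 2L, flip, `*`)
  mg <- crossprod(g, z)               # metagene profiles X_{k,l}
  dimnames(g) <- list(rownames(x)[keep], paste0("PC", seq_len(n)))
  dimnames(mg) <- list(paste0("PC", seq_len(n)), colnames(x))
  new("SubspaceModel", nDim = n, loadings = g, metagenes = mg,
      eigenvalues = ev, geneMeans = stats::setNames(mu, rownames(x)),
      geneSds = stats::setNames(sds, rownames(x)),
      droppedGenes = rownames(x)[!keep])
}

#' Split expression into projected and residual components
#'
#' For each gene i the centered expression row is projected onto the span
#' of the (centered) metagene profiles by least squares: r_i solves
#' min || t(X) r - (x_i - <x_i>) ||, and x_p,i = t(X) r_i,
#' x_r,i = x_i - x_p,i. The gene mean therefore lives in the residual
#' component, which makes the orthogonality of the centered residual to
#' the metagene span exact; differential-expression tests are location
#' tests, so a constant per-gene offset in x_r does not affect any
#' downstream p-value.
#'
#' @param study the \linkS4class{ExpressionStudy} to decompose; must have
#'   the same samples (in order) as the model's fit.
#' @param model a \linkS4class{SubspaceModel} from
#'   \code{\link{fitSubspace}}.
#' @return A \linkS4class{DecomposedExpression} with
#'   \code{projected + residual} reproducing the input exactly.
#' @export
splitExpression <- function(study, model) {
  stopifnot(is(study, "ExpressionStudy"), is(model, "SubspaceModel"))
  x <- exprMatrix(study)
  if (!identical(colnames(x), colnames(model@metagenes)))
    stop("study samples do not match the samples the model was fitted on")
  xc <- model@metagenes - rowMeans(model@metagenes)  # centered profiles
  a <- t(xc)                                         # samples x n
  yc <- x - rowMeans(x)
  qa <- qr(a)
  if (qa$rank < ncol(a)) {
    warning("metagene profiles are rank deficient; using minimum-norm least squares")
    sv <- svd(a)
    pos <- sv$d > max(sv$d) * 1e-12
    pinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    coeffs <- pinv %*% t(yc)
  } else {
    coeffs <- qr.coef(qa, t(yc))                     # n x genes
  }
  xp <- t(a %*% coeffs)
  xr <- x - xp
  dimnames(xp) <- dimnames(xr) <- dimnames(x)
  coeffs <- t(coeffs)
  dimnames(coeffs) <- list(rownames(x), rownames(model@metagenes))
  new("DecomposedExpression", projected = xp, residual = xr,
      coefficients = coeffs)
}
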