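#' Two-sided Welch t-test p-value
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite degrees of
#' freedom. Degenerate inputs follow fixed rules: both groups with zero
#' variance and equal means give p = 1; zero variance with unequal means
#' gives the p-value floor.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param pFloor lower clamp for p-values, default 1e-300 (keeps log10 p
#'   finite).
#' @return A single p-value in [pFloor, 1].
#' @examples
#' welchP(c(1, 2, 3), c(2, 3, 4))
#' @export
welchP <- function(a, b, pFloor = 1e-300) {
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least 2 values")
  drop(rowWelchP(matrix(c(a, b), nrow = 1L), seq_along(a),
                 length(a) + seq_along(b), pFloor = pFloor))
}

#' Row-wise Welch t-test p-values
#'
#' Vectorized Welch test over the rows of a matrix, comparing the columns
#' in \code{idx1} against those in \code{idx2}. Same degenerate-case rules
#' as \code{\link{welchP}}.
#'
#' @param mat numeric matrix (features x samples).
#' @param idx1,idx2 column indices of the two groups (>= 2 each).
#' @param pFloor lower clamp for p-values.
#' @return Numeric vector of p-values, one per row.
#' @export
rowWelchP <- function(mat, idx1, idx2, pFloor = 1e-300) {
  n1 <- length(idx1); n2 <- length(idx2)
  if (n1 < 2L || n2 < 2L) stop("both groups need at least 2 samples")
  x1 <- mat[, idx1, drop = FALSE]
  x2 <- mat[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  delta <- m1 - m2
  eq <- abs(delta) <= 1e-12 * pmax(1, abs(m1), abs(m2))
  p <- numeric(nrow(mat))
  # variances at double-precision roundoff scale count as zero, so that
  # an exactly reconstructed constant row tests as constant
  degen <- se2 <= 1e-20 * pmax(1, m1^2, m2^2)
  p[degen] <- ifelse(eq[degen], 1, pFloor)
  if (any(!degen)) {
    i <- !degen
    df <- se2[i]^2 /
      ((v1[i] / n1)^2 / (n1 - 1L) + (v2[i] / n2)^2 / (n2 - 1L))
    tt <- delta[i] / sqrt(se2[i])
    p[i] <- 2 * stats::pt(-abs(tt), df)
  }
  p <- pmin(pmax(p, pFloor), 1)
  names(p) <- rownames(mat)
  p
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Mann-Whitney/Wilcoxon rank-sum test: exact distribution when the
#' combined sample size is at most 20 and there are no ties, normal
#' approximation with tie and continuity correction otherwise. All values
#' tied across both groups give p = 1.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return A single p-value in (0, 1].
#' @examples
#' wilcoxonP(c(1, 2), c(3, 4))  # exact: 1/3
#' @export
wilcoxonP <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least 2 values")
  if (length(unique(c(a, b))) == 1L) return(1)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 20L && !ties
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  if (!is.finite(p)) p <- 1
  min(p, 1)
}

#' Differential expression in original, projected and residual space
#'
#' Applies the chosen two-sample test gene-wise to the original
#' expression, the projected component x_p, and the residual component
#' x_r, restricted to the samples of a binary contrast. For each gene and
#' contrast this yields three p-values; their log10 values (lp, lp_p,
#' lp_r) feed the Information Ratio. p-values are clamped to
#' [pFloor, 1] so lp stays finite; no multiplicity adjustment is applied
#' anywhere (the IR and the gene-list ranking are defined on raw
#' p-values).
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param decomp the matching \linkS4class{DecomposedExpression}.
#' @param contrast a \linkS4class{BinaryContrast} whose samples are a
#'   subset of the study's.
#' @param method \code{"welch_t"} (default) or \code{"wilcoxon"}.
#' @param pFloor lower clamp for p-values, default 1e-300.
#' @return A \linkS4class{DifferentialResult}.
#' @export
differentialAllSpaces <- function(study, decomp, contrast,
                                  method = c("welch_t", "wilcoxon"),
                                  pFloor = 1e-300) {
  stopifnot(is(study, "ExpressionStudy"),
            is(decomp, "DecomposedExpression"),
            is(contrast, "BinaryContrast"))
  method <- match.arg(method)
  x <- exprMatrix(study)
  if (!identical(dim(x), dim(decomp@projected)))
    stop("decomposition does not match the study dimensions")
  missing <- setdiff(contrast@sampleIds, colnames(x))
  if (length(missing))
    stop("contrast samples absent from study: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  cols <- match(contrast@sampleIds, colnames(x))
  i1 <- cols[contrast@labels == "class1"]
  i2 <- cols[contrast@labels == "class2"]
  testOne <- function(mat) {
    if (method == "welch_t") {
      rowWelchP(mat, i1, i2, pFloor = pFloor)
    } else {
      p <- vapply(seq_len(nrow(mat)), function(g)
        wilcoxonP(mat[g, i1], mat[g, i2]), numeric(1L))
      pmin(pmax(p, pFloor), 1)
    }
  }
  pO <- testOne(x)
  pP <- testOne(decomp@projected)
  pR <- testOne(decomp@residual)
  new("DifferentialResult", geneIds = rownames(x),
      pOriginal = unname(pO), pProjected = unname(pP),
      pResidual = unname(pR),
      lpOriginal = log10(unname(pO)), lpProjected = log10(unname(pP)),
      lpResidual = log10(unname(pR)),
      method = method, contrastName = contrast@name)
}
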