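#' Construct an ExpressionStudy
#'
#' Builds an \linkS4class{ExpressionStudy} from a genes x samples matrix of
#' log2 expression values and an optional phenotype table. Gene and sample
#' identifiers are taken from the matrix dimnames; every sample must be
#' covered by the phenotype table (extra phenotype rows are dropped).
#'
#' @param expr numeric matrix, genes x samples, log2 scale, with unique
#'   rownames (genes) and colnames (samples).
#' @param phenotypes \code{data.frame} with a \code{sample_id} column (or
#'   sample ids as rownames) and arbitrary phenotype columns; \code{NULL}
#'   for a study without phenotypes.
#' @param studyId single character label.
#' @return An \linkS4class{ExpressionStudy}.
#' @examples
#' m <- matrix(rnorm(6, 8), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' ExpressionStudy(m, data.frame(sample_id = c("s1", "s2"),
#'                               grade = c(1, 3)), "toy")
#' @export
ExpressionStudy <- function(expr, phenotypes = NULL, studyId = "study") {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expr must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expr must carry gene identifiers as rownames and sample identifiers as colnames")
  if (anyDuplicated(rownames(expr)))
    stop("duplicated gene identifiers: ",
         paste(utils::head(unique(rownames(expr)[duplicated(rownames(expr))]), 3L),
               collapse = ", "))
  if (anyDuplicated(colnames(expr)))
    stop("duplicated sample identifiers: ",
         paste(utils::head(unique(colnames(expr)[duplicated(colnames(expr))]), 3L),
               collapse = ", "))
  if (!all(is.finite(expr))) {
    bad <- which(!apply(is.finite(expr), 1L, all))
    stop("non-finite expression values in gene(s): ",
         paste(utils::head(rownames(expr)[bad], 3L), collapse = ", "))
  }
  sid <- colnames(expr)
  if (is.null(phenotypes)) {
    cd <- S4Vectors::DataFrame(row.names = sid)
  } else {
    phenotypes <- as.data.frame(phenotypes)
    if ("sample_id" %in% colnames(phenotypes)) {
      rn <- as.character(phenotypes[["sample_id"]])
      phenotypes <- phenotypes[, setdiff(colnames(phenotypes), "sample_id"),
                               drop = FALSE]
    } else {
      rn <- rownames(phenotypes)
    }
    if (anyDuplicated(rn)) stop("duplicated sample_id in phenotype table")
    missing <- setdiff(sid, rn)
    if (length(missing))
      stop("samples absent from the phenotype table: ",
           paste(utils::head(missing, 3L), collapse = ", "))
    phenotypes <- phenotypes[match(sid, rn), , drop = FALSE]
    cd <- S4Vectors::DataFrame(phenotypes, row.names = sid)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = expr), colData = cd)
  new("ExpressionStudy", se, studyId = as.character(studyId))
}

#' Read an expression matrix from TSV
#'
#' Reads a tab-separated expression file: first column \code{gene_id},
#' header row of sample identifiers, numeric body with '.' as decimal
#' separator. Values are taken as already log2-transformed unless
#' \code{log2Transform} is set, in which case log2(x + 1) is applied (for
#' raw-scale input). Any non-numeric body cell (including \code{NA}) is a
#' parse error naming the offending gene and sample.
#'
#' @param path path to the TSV file.
#' @param log2Transform apply log2(x + 1)? Default \code{FALSE}.
#' @param phenotypes optional phenotype table (see
#'   \code{\link{ExpressionStudy}}).
#' @param studyId study label; defaults to the file name without
#'   extension.
#' @return An \linkS4class{ExpressionStudy}.
#' @seealso \code{\link{loadPhenotypes}}
#' @export
loadExpression <- function(path, log2Transform = FALSE, phenotypes = NULL,
                           studyId = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop("expression TSV needs a gene_id column plus at least one sample")
  geneIds <- raw[[1L]]
  sampleIds <- colnames(raw)[-1L]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("malformed numeric value '%s' at gene '%s', sample '%s'",
                 body[i, j], geneIds[i], sampleIds[j]))
  }
  dimnames(num) <- list(geneIds, sampleIds)
  if (log2Transform) num <- log2(num + 1)
  ExpressionStudy(num, phenotypes = phenotypes, studyId = studyId)
}

#' Read a phenotype table from TSV
#'
#' Reads a tab-separated phenotype table with a mandatory
#' \code{sample_id} column; empty cells and \code{NA} are treated as
#' missing values.
#'
#' @param path path to the TSV file.
#' @return A \code{data.frame} with one row per sample.
#' @export
loadPhenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", ""), check.names = FALSE)
  if (!"sample_id" %in% colnames(df))
    stop("phenotype table must contain a sample_id column")
  df[["sample_id"]] <- as.character(df[["sample_id"]])
  df
}

#' Collapse probe sets to gene symbols
#'
#' Maps probe-level rows to gene symbols. When several probe sets share a
#' symbol, the probe with the largest mean expression over all samples is
#' kept as the representative; exact ties are broken by the
#' lexicographically smallest probe identifier. Probes without a symbol in
#' the mapping are dropped.
#'
#' @param study an \linkS4class{ExpressionStudy} with probe-level rows.
#' @param mapping \code{data.frame} with columns \code{probe_id} and
#'   \code{symbol}.
#' @return An \linkS4class{ExpressionStudy} with one row per symbol
#'   (symbols in sorted order).
#' @export
collapseProbesets <- function(study, mapping) {
  stopifnot(is(study, "ExpressionStudy"))
  mapping <- as.data.frame(mapping)
  if (!all(c("probe_id", "symbol") %in% colnames(mapping)))
    stop("mapping must have columns probe_id and symbol")
  mapping <- mapping[!is.na(mapping$symbol) & nzchar(mapping$symbol), ,
                     drop = FALSE]
  if (!nrow(mapping)) stop("probe mapping is empty")
  mapping$probe_id <- as.character(mapping$probe_id)
  mapping$symbol <- as.character(mapping$symbol)
  x <- exprMatrix(study)
  mapping <- mapping[mapping$probe_id %in% rownames(x), , drop = FALSE]
  if (!nrow(mapping)) stop("no probe in the mapping matches the study")
  m <- rowMeans(x)[mapping$probe_id]
  # largest mean first, then lexicographically smallest probe id
  ord <- order(mapping$symbol, -m, mapping$probe_id)
  mapping <- mapping[ord, , drop = FALSE]
  keep <- mapping[!duplicated(mapping$symbol), , drop = FALSE]
  out <- x[keep$probe_id, , drop = FALSE]
  rownames(out) <- keep$symbol
  out <- out[order(rownames(out)), , drop = FALSE]
  ExpressionStudy(out, phenotypes = .phenoWithSampleId(study),
                  studyId = studyId(study))
}

# phenotype table in constructor-ready form (or NULL when empty)
.phenoWithSampleId <- function(study) {
  df <- phenoTable(study)
  if (!ncol(df) && !nrow(df)) return(NULL)
  cbind(data.frame(sample_id = colnames(study), stringsAsFactors = FALSE),
        df)
}

#' Remove duplicated samples across and within studies
#'
#' Flags sample pairs whose squared Pearson correlation over the shared
#' gene set reaches \code{r2Threshold} and removes one member per pair.
#' Candidates are scanned in a fixed order -- earlier study in the input
#' list first, then lexicographically smaller sample identifier -- and for
#' each correlated pair the later candidate is removed (greedy, so of a
#' chain a~b~c with a not correlated to c, a and c survive).
#'
#' @param studies a list of \linkS4class{ExpressionStudy} objects sharing
#'   one gene set (run \code{\link{intersectGenes}} first), or a single
#'   study.
#' @param r2Threshold squared-correlation threshold, default 0.99.
#' @return The input studies with duplicated samples removed (a list when
#'   a list was given).
#' @export
deduplicateSamples <- function(studies, r2Threshold = 0.99) {
  single <- is(studies, "ExpressionStudy")
  if (single) studies <- list(studies)
  stopifnot(all(vapply(studies, is, logical(1L), "ExpressionStudy")))
  genes <- rownames(studies[[1L]])
  for (s in studies)
    if (!identical(rownames(s), genes))
      stop("studies must share one gene set in one order; run intersectGenes() first")
  idx <- do.call(rbind, lapply(seq_along(studies), function(k)
    data.frame(study = k, sample = colnames(studies[[k]]),
               stringsAsFactors = FALSE)))
  ord <- order(idx$study, idx$sample)
  idx <- idx[ord, , drop = FALSE]
  big <- do.call(cbind, lapply(studies, exprMatrix))[, ord, drop = FALSE]
  r2 <- suppressWarnings(stats::cor(big))^2
  r2[!is.finite(r2)] <- 0  # constant samples carry no correlation evidence
  n <- nrow(idx)
  removed <- logical(n)
  for (i in seq_len(n - 1L)) {
    if (removed[i]) next
    hits <- which(!removed & r2[i, ] >= r2Threshold)
    removed[hits[hits > i]] <- TRUE
  }
  dropIds <- split(idx$sample[removed], idx$study[removed])
  out <- lapply(seq_along(studies), function(k) {
    drop <- dropIds[[as.character(k)]]
    if (is.null(drop) || !length(drop)) return(studies[[k]])
    studies[[k]][, setdiff(colnames(studies[[k]]), drop)]
  })
  if (single) out[[1L]] else out
}

#' Remove samples with extreme mean expression
#'
#' Computes the mean expression of every sample and removes samples whose
#' mean deviates from the grand mean of the per-sample means by more than
#' \code{sigma} standard deviations (sd taken over the full sample set in
#' one pass; no re-iteration). Used to drop erroneous chips.
#'
#' @param study an \linkS4class{ExpressionStudy} with at least 3 samples.
#' @param sigma the z-score cutoff, default 5.
#' @return The study without the outlying samples.
#' @export
removeOutlierSamples <- function(study, sigma = 5) {
  stopifnot(is(study, "ExpressionStudy"))
  if (ncol(study) < 3L) stop("need at least 3 samples")
  m <- colMeans(exprMatrix(study))
  s <- stats::sd(m)
  if (!is.finite(s) || s == 0) return(study)  # identical means: no outliers
  out <- abs(m - mean(m)) > sigma * s
  out[is.na(out)] <- FALSE                    # sigma = Inf gives Inf cutoff
  if (!any(out)) return(study)
  if (sum(!out) < 2L) stop("outlier removal would leave fewer than 2 samples")
  study[, !out]
}

#' Restrict studies to their common gene set
#'
#' Intersects the gene sets of the given studies and restricts every study
#' to the shared genes, rows in a canonical sorted order.
#'
#' @param studies a list of \linkS4class{ExpressionStudy} objects (a
#'   single study is returned with rows sorted).
#' @return A list of restricted studies (or a single study).
#' @export
intersectGenes <- function(studies) {
  single <- is(studies, "ExpressionStudy")
  if (single) studies <- list(studies)
  stopifnot(length(studies) >= 1L,
            all(vapply(studies, is, logical(1L), "ExpressionStudy")))
  common <- Reduce(intersect, lapply(studies, rownames))
  if (!length(common)) stop("studies share no genes")
  common <- sort(common)
  out <- lapply(studies, function(s) s[common, ])
  if (single) out[[1L]] else out
}
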