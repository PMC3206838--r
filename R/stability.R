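#' Top-ranked gene list
#'
#' Ranks genes by increasing original-space p-value (ties broken by gene
#' identifier) and keeps the head of length
#' max(1, floor(fraction * n_genes)).
#'
#' @param de a \linkS4class{DifferentialResult}.
#' @param fraction fraction of the gene universe to keep, in (0, 1],
#'   default 0.05 (the top 5 percent).
#' @param sourceStudy label recorded in the list.
#' @return A \linkS4class{RankedGeneList}.
#' @export
topGeneList <- function(de, fraction = 0.05, sourceStudy = NA_character_) {
  stopifnot(is(de, "DifferentialResult"))
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  ord <- order(de@pOriginal, de@geneIds)
  len <- max(1L, floor(fraction * length(de@geneIds)))
  new("RankedGeneList", geneIds = de@geneIds[ord][seq_len(len)],
      fraction = fraction, sourceStudy = sourceStudy,
      contrastName = de@contrastName)
}

#' Percentage of overlapping genes (POG)
#'
#' The stability metric between two equal-length top-ranked gene lists:
#' 100 * |intersection| / list length.
#'
#' @param listA,listB \linkS4class{RankedGeneList} objects of equal
#'   length, drawn from the same gene universe.
#' @return The overlap percentage in [0, 100].
#' @export
pog <- function(listA, listB) {
  stopifnot(is(listA, "RankedGeneList"), is(listB, "RankedGeneList"))
  if (length(listA@geneIds) != length(listB@geneIds))
    stop("gene lists differ in length (", length(listA@geneIds), " vs ",
         length(listB@geneIds), ")")
  100 * length(intersect(listA@geneIds, listB@geneIds)) /
    length(listA@geneIds)
}

#' Pairwise gene-list stability across studies
#'
#' For every unordered pair of studies and every applicable contrast:
#' computes each study's Information Ratio and top-fraction gene list,
#' then reports the pair's POG together with the mean of the two IRs.
#' Pairs where a contrast cannot be built in one of the studies (missing
#' variable, class too small) are skipped with a notice.
#'
#' @param studies a list of at least two \linkS4class{ExpressionStudy}
#'   objects sharing one gene set (run \code{\link{intersectGenes}}
#'   first).
#' @param contrastSpecs a \linkS4class{ContrastSpec}, contrast name, or a
#'   list of either.
#' @param n subspace dimension, default 4.
#' @param fraction top-list fraction, default 0.05.
#' @param method test method passed down.
#' @return A \code{data.frame} with columns \code{study_a},
#'   \code{study_b}, \code{contrast}, \code{mean_ir}, \code{pog}.
#' @export
pairwiseStability <- function(studies, contrastSpecs, n = 4,
                              fraction = 0.05, method = "welch_t") {
  stopifnot(is.list(studies), length(studies) >= 2L,
            all(vapply(studies, is, logical(1L), "ExpressionStudy")))
  genes <- rownames(studies[[1L]])
  for (s in studies)
    if (!identical(rownames(s), genes))
      stop("studies must share one gene set; run intersectGenes() first")
  if (!is.list(contrastSpecs) || is(contrastSpecs, "ContrastSpec"))
    contrastSpecs <- list(contrastSpecs)
  contrastSpecs <- lapply(contrastSpecs, function(cs)
    if (is.character(cs)) builtinContrasts(cs) else cs)

  # per study x contrast: IR and top list (subspace fitted once per study,
  # implicitly inside irForContrast; contrasts reuse the same model via
  # the scan below)
  cells <- list()
  for (si in seq_along(studies)) {
    study <- studies[[si]]
    model <- fitSubspace(study, n = n)
    decomp <- splitExpression(study, model)
    for (cs in contrastSpecs) {
      contrast <- tryCatch(binarizePhenotype(study, cs), error = function(e) {
        message("skipping contrast '", cs@name, "' in study '",
                studyId(study), "': ", conditionMessage(e))
        NULL
      })
      if (is.null(contrast)) next
      de <- differentialAllSpaces(study, decomp, contrast, method = method)
      lpw <- stats::setNames(de@lpOriginal, de@geneIds)
      wm <- fitLambda(lpw)
      irRes <- informationRatio(de, wm, nDim = n)
      cells[[paste(si, cs@name, sep = "\r")]] <- list(
        study = si, contrast = cs@name, ir = irValue(irRes),
        top = topGeneList(de, fraction, sourceStudy = studyId(study)))
    }
  }

  rows <- list()
  for (ci in unique(vapply(cells, `[[`, character(1L), "contrast"))) {
    sub <- Filter(function(c) c$contrast == ci, cells)
    ss <- vapply(sub, `[[`, numeric(1L), "study")
    if (length(sub) < 2L) next
    for (i in seq_len(length(sub) - 1L)) {
      for (j in seq(i + 1L, length(sub))) {
        rows[[length(rows) + 1L]] <- data.frame(
          study_a = studyId(studies[[ss[i]]]),
          study_b = studyId(studies[[ss[j]]]),
          contrast = ci,
          mean_ir = mean(c(sub[[i]]$ir, sub[[j]]$ir)),
          pog = pog(sub[[i]]$top, sub[[j]]$top),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(study_a = character(), study_b = character(),
                      contrast = character(), mean_ir = numeric(),
                      pog = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
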