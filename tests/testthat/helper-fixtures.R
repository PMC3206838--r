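# fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir()

# small random study: pure noise around 8 log2 units unless a signal is
# injected by the caller
randomStudy <- function(nGenes = 50, nSamples = 20, seed = 1,
                        studyId = "rnd") {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * nSamples, mean = 8), nGenes, nSamples,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("s%03d", seq_len(nSamples))))
  ExpressionStudy(m, studyId = studyId)
}

# study with an attached two-class phenotype column
labelledStudy <- function(nGenes = 50, nSamples = 20, seed = 1,
                          n1 = nSamples %/% 2, studyId = "lab") {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * nSamples, mean = 8), nGenes, nSamples,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("s%03d", seq_len(nSamples))))
  ph <- data.frame(sample_id = colnames(m),
                   group = rep(c("class1", "class2"),
                               c(n1, nSamples - n1)))
  ExpressionStudy(m, phenotypes = ph, studyId = studyId)
}

contrastOf <- function(study, name = "group_c1_vs_c2") {
  binarizePhenotype(study, name)
}

writeExprTSV <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

writePhenoTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# DifferentialResult straight from lp values (for statistic-level tests)
deFromLp <- function(lpProj, lpResid, lpOrig = lpProj,
                     geneIds = sprintf("g%03d", seq_along(lpProj)),
                     contrastName = "toy") {
  new("DifferentialResult", geneIds = geneIds,
      pOriginal = 10^lpOrig, pProjected = 10^lpProj, pResidual = 10^lpResid,
      lpOriginal = lpOrig, lpProjected = lpProj, lpResidual = lpResid,
      method = "welch_t", contrastName = contrastName)
}

# WeightModel with explicit weights (for statistic-level tests)
wmFromWeights <- function(w, lambda = 0) {
  new("WeightModel", lambda = lambda, nBins = 2L, binEdges = c(0, 1, 2),
      binRatios = c(0.5, 0.5), weights = as.numeric(w))
}

# differential result for a simulated study via the standard pipeline
deForSim <- function(sim, n = 4) {
  model <- fitSubspace(sim$study, n = n)
  decomp <- splitExpression(sim$study, model)
  differentialAllSpaces(sim$study, decomp, sim$contrast)
}

shuffledContrast <- function(contrast, seed) {
  set.seed(seed)
  new("BinaryContrast", name = "shuffled",
      sampleIds = contrast@sampleIds,
      labels = sample(contrast@labels))
}
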