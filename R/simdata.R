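#' Construct a simulator configuration
#'
#' Defaults describe the reference synthetic study used throughout the
#' package's tests: 2000 genes x 100 samples, four latent factors with
#' factor-score sd 3 against unit gene-level noise, a balanced binary
#' phenotype, 100 signal genes, and a class shift of two noise sds.
#'
#' @param nGenes,nSamples matrix dimensions.
#' @param dim intrinsic dimensionality (number of latent factors), 1-100.
#' @param noiseSd,factorSd noise and factor-score standard deviations.
#' @param signalMode \code{"subspace"} (phenotype tied to the latent
#'   factors) or \code{"residual"} (phenotype signal orthogonal to the
#'   factor span).
#' @param effectSize class-2 mean shift on the signal genes, in units of
#'   \code{noiseSd}.
#' @param nSignalGenes number of signal genes.
#' @param balance class-1 fraction.
#' @param signalFactors in subspace mode, how many leading factors the
#'   phenotype loads on.
#' @param seed integer RNG seed.
#' @return A \linkS4class{SimConfig}.
#' @export
simConfig <- function(nGenes = 2000, nSamples = 100, dim = 4,
                      noiseSd = 1.0, factorSd = 3.0,
                      signalMode = c("subspace", "residual"),
                      effectSize = 2.0, nSignalGenes = 100,
                      balance = 0.5, signalFactors = 1, seed = 1) {
  new("SimConfig", nGenes = as.integer(nGenes),
      nSamples = as.integer(nSamples), dim = as.integer(dim),
      noiseSd = noiseSd, factorSd = factorSd,
      signalMode = match.arg(signalMode), effectSize = effectSize,
      nSignalGenes = as.integer(nSignalGenes), balance = balance,
      signalFactors = as.integer(signalFactors), seed = as.integer(seed))
}

# one simulated study; `shared` optionally fixes the signal gene set, the
# first-factor loading column, or the residual-mode shift signs (used by
# simulateStudyPair to give two studies common signal structure)
.simulateCore <- function(cfg, seed, shared = list()) {
  set.seed(as.integer(seed))
  nG <- cfg@nGenes; nS <- cfg@nSamples; d <- cfg@dim
  gids <- sprintf("gene_%05d", seq_len(nG))
  sids <- sprintf("sample_%04d", seq_len(nS))
  if (!is.null(shared$L)) {
    L <- shared$L
  } else {
    L <- matrix(stats::rnorm(nG * d), nG, d)
    L <- scale(L)                     # unit-variance loading columns
    attr(L, "scaled:center") <- attr(L, "scaled:scale") <- NULL
  }
  fac <- matrix(stats::rnorm(d * nS), d, nS)
  noise <- matrix(stats::rnorm(nG * nS, sd = cfg@noiseSd), nG, nS)
  expr <- cfg@factorSd * (L %*% fac) + noise + 8
  if (cfg@signalMode == "subspace") {
    # phenotype tied to the leading factor scores: class 2 is the
    # high-score side of the balance quantile, so the class difference of
    # every gene runs through its factor loadings, i.e. inside the
    # leading-variance span. The phenotype's marker genes are therefore
    # the strongest loaders on the label-linked factor combination; those
    # are the signal genes, and they get an extra shift along that
    # loading pattern.
    score <- colMeans(fac[seq_len(cfg@signalFactors), , drop = FALSE])
    isC2 <- score > stats::quantile(score, cfg@balance)
    base <- rowSums(L[, seq_len(cfg@signalFactors), drop = FALSE])
    signalIdx <- sort(order(-abs(base))[seq_len(cfg@nSignalGenes)])
    u <- base[signalIdx]
    u <- u / sqrt(mean(u^2))
    if (any(isC2))
      expr[signalIdx, isC2] <- expr[signalIdx, isC2] +
        cfg@effectSize * cfg@noiseSd * u
  } else {
    signalIdx <- if (!is.null(shared$signalIdx)) shared$signalIdx
                 else sort(sample.int(nG, cfg@nSignalGenes))
    # random labels; per-gene shifts with random signs, applied along the
    # class-indicator direction orthogonalized against the factor span,
    # so the class difference avoids the leading factors entirely
    n1 <- round(cfg@balance * nS)
    perm <- sample.int(nS)
    isC2 <- rep(TRUE, nS)
    isC2[perm[seq_len(n1)]] <- FALSE
    signs <- if (!is.null(shared$signs)) shared$signs
             else sample(c(-1, 1), cfg@nSignalGenes, replace = TRUE)
    i2c <- as.numeric(isC2) - mean(isC2)
    fc <- fac - rowMeans(fac)
    w0 <- qr.resid(qr(t(fc)), i2c)
    d0 <- mean(w0[isC2]) - mean(w0[!isC2])
    if (!is.finite(d0) || abs(d0) < 1e-8)
      stop("class indicator lies inside the factor span; cannot place a residual signal")
    w <- w0 / d0                      # class-mean difference of w is 1
    expr[signalIdx, ] <- expr[signalIdx, ] +
      (cfg@effectSize * cfg@noiseSd * signs) %o% w
    shiftProfile <- w
  }
  dimnames(expr) <- list(gids, sids)
  pheno <- data.frame(sample_id = sids,
                      group = ifelse(isC2, "class2", "class1"),
                      stringsAsFactors = FALSE)
  study <- ExpressionStudy(expr, phenotypes = pheno,
                           studyId = sprintf("sim_%s_d%d_s%d",
                                             cfg@signalMode, d, seed))
  contrast <- new("BinaryContrast", name = "group_c1_vs_c2",
                  sampleIds = sids,
                  labels = factor(ifelse(isC2, "class2", "class1"),
                                  levels = c("class1", "class2")))
  list(study = study, contrast = contrast, signalGenes = gids[signalIdx],
       factors = fac,
       shiftProfile = if (cfg@signalMode == "residual") shiftProfile)
}

#' Simulate one expression study with controlled signal placement
#'
#' Generates expression as factorSd * L F + E + 8: L is a genes x dim
#' loading matrix with standard-normal entries and unit-variance columns,
#' F holds standard-normal factor scores, E is independent Gaussian noise
#' with sd \code{noiseSd}, and the offset of 8 log2 units mimics array
#' data. In \code{subspace} mode the binary phenotype is the balance
#' quantile split of the mean of the first \code{signalFactors} factor
#' scores -- so the class difference of every gene lies inside the
#' leading-variance span; the signal genes are the \code{nSignalGenes}
#' strongest loaders on that factor combination (the phenotype's natural
#' marker genes) and receive an extra shift of
#' \code{effectSize * noiseSd} along the loading pattern. In
#' \code{residual} mode the labels are
#' random and the signal genes receive independent per-gene shifts of
#' +/- \code{effectSize * noiseSd} along the class-indicator direction
#' orthogonalized against the factor span, so the class difference avoids
#' the leading factors. All draws come from the seeded generator; the
#' same configuration and seed reproduce the study bit for bit.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return A list with elements \code{study}
#'   (\linkS4class{ExpressionStudy}; the phenotype table has a
#'   \code{group} column), \code{contrast}
#'   (\linkS4class{BinaryContrast}), \code{signalGenes} (the truth gene
#'   set), \code{factors} (the dim x samples matrix of true factor
#'   scores, for validation), and \code{shiftProfile} (residual mode
#'   only: the orthogonalized per-sample shift profile).
#' @examples
#' sim <- simulateStudy(simConfig(nGenes = 300, nSamples = 40, seed = 7))
#' sim$study
#' @export
simulateStudy <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  .simulateCore(cfg, cfg@seed)
}

#' Simulate a pair of studies with shared or independent signal
#'
#' Two studies emulating distinct cohorts. With \code{sharedSignal} the
#' two cohorts measure the same biology: the gene-factor loading matrix
#' is common (in subspace mode this also fixes the signal gene set --
#' the top loaders), and in residual mode the signal gene set and shift
#' signs are shared as well; factor scores, noise and labels are always
#' cohort-specific. Without \code{sharedSignal} everything is redrawn
#' independently. Shared draws derive
#' from \code{cfg@seed}, study-specific draws from \code{seedA} and
#' \code{seedB}.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param sharedSignal share the signal structure? Default \code{TRUE}.
#' @param seedA,seedB per-study seeds.
#' @return A list with elements \code{a} and \code{b}, each as returned
#'   by \code{\link{simulateStudy}}.
#' @export
simulateStudyPair <- function(cfg, sharedSignal = TRUE, seedA = cfg@seed + 1,
                              seedB = cfg@seed + 2) {
  stopifnot(is(cfg, "SimConfig"))
  shared <- list()
  if (sharedSignal) {
    # two cohorts of the same biology: the gene-factor loading structure
    # is common, factor scores / noise / labels are cohort-specific; in
    # subspace mode the shared loadings also fix the signal gene set
    # (the top loaders), in residual mode the signal genes and their
    # shift signs are shared explicitly
    set.seed(cfg@seed)
    L <- matrix(stats::rnorm(cfg@nGenes * cfg@dim), cfg@nGenes, cfg@dim)
    L <- scale(L)
    attr(L, "scaled:center") <- attr(L, "scaled:scale") <- NULL
    shared$L <- L
    if (cfg@signalMode == "residual") {
      shared$signalIdx <- sort(sample.int(cfg@nGenes, cfg@nSignalGenes))
      shared$signs <- sample(c(-1, 1), cfg@nSignalGenes, replace = TRUE)
    }
  }
  list(a = .simulateCore(cfg, seedA, shared),
       b = .simulateCore(cfg, seedB, shared))
}
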