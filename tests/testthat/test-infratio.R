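test_that("fitLambda recovers the rate exactly on a log-linear histogram", {
  # counts 2^(50-j) in bins j = 39..50 are exactly log-linear in the bin
  # midpoints; with bin width log(2) the decay rate is exactly 1
  h <- log(2)
  mids <- (seq_len(50) - 0.5) * h
  counts <- integer(50)
  counts[39:50] <- 2^(50 - (39:50))
  a <- rep(mids, counts)
  a[which.max(a)] <- 50 * h          # pin the upper edge
  wm <- fitLambda(-a, nBins = 50)
  expect_equal(wm@lambda, 1, tolerance = 1e-10)
  expect_equal(sum(wm@binRatios), 1, tolerance = 1e-12)
  # weight identity w_i = exp(lambda |lp|)
  expect_equal(unname(geneWeights(wm)), exp(wm@lambda * a),
               tolerance = 1e-12)
})

test_that("fitLambda recovers an exponential rate from sampled lp values", {
  set.seed(20)
  a <- rexp(20000, rate = 1.5)
  wm <- fitLambda(-a)
  expect_gt(wm@lambda, 1.35)
  expect_lt(wm@lambda, 1.65)

  # independent histogram-regression oracle with base tools
  hobj <- hist(a, breaks = seq(0, max(a), length.out = 51), plot = FALSE)
  keep <- hobj$counts >= 1
  ref <- -unname(coef(lm(log(hobj$counts[keep] / sum(hobj$counts)) ~
                           hobj$mids[keep]))[2])
  expect_equal(wm@lambda, ref, tolerance = 1e-10)
})

test_that("fitLambda rejects degenerate inputs", {
  expect_error(fitLambda(rep(-1, 50)), "at least 100")
  expect_error(fitLambda(rep(-1, 200)), "occupied bins")
  expect_error(fitLambda(rep(0, 200)), "occupied bins")
  expect_error(fitLambda(c(rep(-1, 200), 0.5)), "<= 0")
})

test_that("expected total weight per occupied bin is flat for matched lambda", {
  set.seed(8)
  a <- rexp(20000, rate = 1.5)
  wm <- fitLambda(-a)
  bin <- findInterval(a, wm@binEdges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, wm@nBins)
  wsum <- vapply(seq_len(wm@nBins), function(j)
    sum(geneWeights(wm)[bin == j]), numeric(1))
  # Poisson noise limits the check to well-populated bins
  well <- counts >= 100
  expect_gt(sum(well), 5)
  dev <- abs(wsum[well] / mean(wsum[well]) - 1)
  expect_lt(max(dev), 0.2)
})

test_that("information ratio boundary identities hold exactly", {
  # lp_proj = lp_resid for every gene: each ratio is 1/2
  lp <- -c(0.5, 1, 2, 4, 8)
  de <- deFromLp(lp, lp)
  expect_equal(irValue(informationRatio(de, wmFromWeights(c(5, 4, 3, 2, 1)))),
               0.5)
  # all information in the projected space
  de0 <- deFromLp(lpProj = -c(1, 2, 3), lpResid = c(0, 0, 0))
  expect_equal(irValue(informationRatio(de0, wmFromWeights(c(1, 1, 1)))), 0)
  # all information in the residual space
  de1 <- deFromLp(lpProj = c(0, 0, 0), lpResid = -c(1, 2, 3))
  expect_equal(irValue(informationRatio(de1, wmFromWeights(c(1, 1, 1)))), 1)
})

test_that("information ratio matches the hand-evaluated 3-gene example", {
  de <- deFromLp(lpProj = c(-4, -1, 0), lpResid = c(-1, -1, -2))
  res <- informationRatio(de, wmFromWeights(c(2, 1, 1)))
  expect_equal(irValue(res), 0.475, tolerance = 1e-12)
  expect_identical(res@nGenesUsed, 3L)
  # spreadsheet-style oracle: explicit elementwise evaluation
  q <- abs(c(-1, -1, -2)) / (abs(c(-1, -1, -2)) + abs(c(-4, -1, 0)))
  expect_equal(irValue(res), sum(c(2, 1, 1) * q) / 4, tolerance = 1e-15)
})

test_that("information ratio invariances and exclusions", {
  set.seed(14)
  lpP <- -rexp(300); lpR <- -rexp(300)
  de <- deFromLp(lpP, lpR)
  w <- runif(300, 1, 5)
  ir1 <- irValue(informationRatio(de, wmFromWeights(w)))
  # uniform weight rescaling
  expect_equal(irValue(informationRatio(de, wmFromWeights(w * 7))), ir1,
               tolerance = 1e-12)
  # swapping the spaces maps IR to 1 - IR
  deSwap <- deFromLp(lpR, lpP)
  expect_equal(irValue(informationRatio(deSwap, wmFromWeights(w))),
               1 - ir1, tolerance = 1e-12)
  # IR stays inside [0, 1] over random inputs
  for (i in 1:25) {
    deR <- deFromLp(-rexp(120, runif(1, 0.3, 3)),
                    -rexp(120, runif(1, 0.3, 3)))
    v <- irValue(informationRatio(deR, wmFromWeights(runif(120, 1, 10))))
    expect_gte(v, 0); expect_lte(v, 1)
  }
  # degenerate genes are excluded, not averaged in as 1/2
  deMix <- deFromLp(c(-2, 0, 0), c(0, 0, 0))
  resMix <- informationRatio(deMix, wmFromWeights(c(1, 1, 1)))
  expect_identical(resMix@nGenesUsed, 1L)
  expect_equal(irValue(resMix), 0)
  expect_error(informationRatio(deFromLp(c(0, 0), c(0, 0)),
                                wmFromWeights(c(1, 1))),
               "no informative genes")
})

test_that("irForContrast separates subspace- from residual-placed signal", {
  simS <- simulateStudy(simConfig(nGenes = 600, nSamples = 80,
                                  signalMode = "subspace",
                                  nSignalGenes = 30, seed = 1))
  resS <- irForContrast(simS$study, simS$contrast, n = 4)
  expect_lte(irValue(resS), 0.25)
  expect_identical(typeLabel(resS), "type1_low")

  simR <- simulateStudy(simConfig(nGenes = 600, nSamples = 80,
                                  signalMode = "residual",
                                  nSignalGenes = 30, seed = 1))
  resR <- irForContrast(simR$study, simR$contrast, n = 4)
  expect_gte(irValue(resR), 0.5)
  expect_identical(typeLabel(resR), "type2_3_high")

  # the attached differential result covers all genes
  de <- attr(resS, "differential")
  expect_s4_class(de, "DifferentialResult")
  expect_length(de@geneIds, 600)
})

test_that("irDimensionScan is consistent with single computations and total", {
  sim <- simulateStudy(simConfig(nGenes = 400, nSamples = 60, seed = 3))
  single <- irForContrast(sim$study, sim$contrast, n = 4)
  scan <- irDimensionScan(sim$study, sim$contrast, nRange = 4)
  expect_equal(scan$ir, irValue(single), tolerance = 1e-12)

  # pure-noise data: the scan completes with finite values
  noise <- labelledStudy(300, 40, seed = 9)
  bc <- contrastOf(noise)
  scanN <- irDimensionScan(noise, bc, nRange = 1:5)
  expect_identical(scanN$n, 1:5)
  expect_true(all(is.finite(scanN$ir)))

  expect_error(irDimensionScan(noise, bc, nRange = 1:60), "n_samples - 1")
})

test_that("labels carrying no signal never look subspace-informative", {
  # on pure noise the IR is indeterminate-to-high, never low: the
  # projection removes n of the sample-space directions, so what null
  # significance there is concentrates mildly in the residual. The
  # essential property is that a null contrast is never classified as a
  # low-IR (stable-biomarker) phenotype.
  irs <- vapply(1:5, function(s) {
    st <- labelledStudy(1000, 60, seed = 100 + s)
    irValue(irForContrast(st, contrastOf(st), n = 4))
  }, numeric(1))
  expect_true(all(irs > 0.3 & irs < 0.95))
  expect_gt(mean(irs), 0.5)
})
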