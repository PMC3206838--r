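test_that("SVD route matches an explicit correlation-matrix eigendecomposition", {
  st <- randomStudy(50, 20, seed = 11)
  n <- 5
  model <- fitSubspace(st, n = n)

  # brute-force oracle: form the 50 x 50 correlation matrix and decompose
  x <- exprMatrix(st)
  C <- cor(t(x))
  eig <- eigen(C, symmetric = TRUE)
  expect_equal(eigenvalues(model), eig$values[1:n], tolerance = 1e-8)

  # principal angles between the two n-dimensional loading subspaces
  qa <- qr.Q(qr(loadings(model)))
  qb <- qr.Q(qr(eig$vectors[, 1:n]))
  angles <- acos(pmin(1, svd(crossprod(qa, qb))$d))
  expect_lt(max(angles), 1e-6)

  # loadings orthonormal, eigenvalues decreasing
  expect_equal(crossprod(loadings(model)), diag(n), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(eigenvalues(model)) <= 1e-10))

  # metagene profile k is the loadings-weighted sum of standardized rows
  z <- (x - rowMeans(x)) / apply(x, 1, sd)
  expect_equal(metagenes(model), crossprod(loadings(model), z),
               tolerance = 1e-10)
})

test_that("rank-1 data yields the sign-pattern eigenvector with eigenvalue ~ N", {
  set.seed(5)
  u <- rnorm(40); v <- rnorm(15)
  x <- outer(u, v) + matrix(rnorm(40 * 15, sd = 1e-6), 40, 15) + 8
  dimnames(x) <- list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:15))
  model <- fitSubspace(ExpressionStudy(x), n = 1)
  # standardized rows are +/- the same profile: top eigenvalue ~ n_genes
  expect_equal(eigenvalues(model)[1], 40, tolerance = 1e-3)
  g <- loadings(model)[, 1]
  expect_equal(abs(g), rep(1 / sqrt(40), 40), tolerance = 1e-3,
               ignore_attr = TRUE)
  s <- sign(g * u)
  expect_true(all(s == s[1]))        # matches the sign pattern of u
})

test_that("trace is conserved at full rank and constant genes are dropped", {
  st <- randomStudy(30, 12, seed = 2)
  model <- fitSubspace(st, n = 11)
  expect_equal(sum(eigenvalues(model)), 30, tolerance = 1e-6)

  x <- exprMatrix(st); x[3, ] <- 4
  stc <- ExpressionStudy(x, studyId = "const")
  expect_warning(mc <- fitSubspace(stc, n = 3), "constant gene")
  expect_identical(mc@droppedGenes, rownames(x)[3])
  expect_identical(nrow(loadings(mc)), 29L)

  expect_error(fitSubspace(st, n = 12), "must lie in")
  expect_error(fitSubspace(st, n = 0), "must lie in")
})

test_that("splitExpression matches the normal-equations oracle and reconstructs", {
  st <- randomStudy(30, 12, seed = 8)
  model <- fitSubspace(st, n = 3)
  dec <- splitExpression(st, model)
  x <- exprMatrix(st)

  # exact reconstruction
  expect_equal(projectedPart(dec) + residualPart(dec), x,
               tolerance = 1e-12)

  # oracle: explicit hat matrix from the centered metagene profiles
  xc <- metagenes(model) - rowMeans(metagenes(model))
  hat <- t(xc) %*% solve(xc %*% t(xc)) %*% xc
  yc <- x - rowMeans(x)
  expect_lt(max(abs(projectedPart(dec) - yc %*% hat)), 1e-8)

  # centered residual orthogonal to every centered metagene profile
  rc <- residualPart(dec) - rowMeans(residualPart(dec))
  expect_lt(max(abs(rc %*% t(xc))), 1e-8)

  # per-gene variance additivity (Pythagoras on centered data)
  vx <- apply(x, 1, var)
  vp <- apply(projectedPart(dec), 1, var)
  vr <- apply(residualPart(dec), 1, var)
  expect_equal(vp + vr, vx, tolerance = 1e-8)
})

test_that("data inside the metagene span leaves only the per-gene mean in x_r", {
  st <- randomStudy(40, 16, seed = 3)
  model <- fitSubspace(st, n = 4)
  coef <- matrix(rnorm(40 * 4), 40, 4)
  x <- coef %*% metagenes(model) + rnorm(40)   # exact combination + offsets
  dimnames(x) <- list(rownames(st), colnames(st))
  st2 <- ExpressionStudy(x, studyId = "span")
  dec <- splitExpression(st2, model)
  rc <- residualPart(dec) - rowMeans(residualPart(dec))
  expect_lt(max(abs(rc)), 1e-8)
  expect_equal(residualPart(dec), matrix(rowMeans(x), 40, 16,
                                         dimnames = dimnames(x)),
               tolerance = 1e-8)
})

test_that("a gene orthogonal to the metagene span is pure residual", {
  st <- randomStudy(25, 10, seed = 4)
  model <- fitSubspace(st, n = 3)
  xc <- metagenes(model) - rowMeans(metagenes(model))
  v <- rnorm(10)
  v <- qr.resid(qr(t(xc)), v - mean(v))        # orthogonal to the span
  x <- exprMatrix(st); x[1, ] <- v + 8
  st2 <- ExpressionStudy(x, studyId = "orth")
  dec <- splitExpression(st2, model)
  expect_lt(max(abs(projectedPart(dec)[1, ])), 1e-8)
  expect_equal(residualPart(dec)[1, ], x[1, ], tolerance = 1e-10)
})

test_that("the split depends on the subspace, not the eigenvector basis", {
  st <- randomStudy(60, 18, seed = 9)
  model <- fitSubspace(st, n = 4)
  dec <- splitExpression(st, model)

  # rotate the loading columns by a random orthonormal Q
  set.seed(21)
  q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  rot <- model
  rot@loadings <- model@loadings %*% q
  rot@metagenes <- crossprod(q, model@metagenes)
  dimnames(rot@metagenes) <- dimnames(model@metagenes)
  decR <- splitExpression(st, rot)
  expect_lt(max(abs(projectedPart(decR) - projectedPart(dec))), 1e-8)
  expect_lt(max(abs(residualPart(decR) - residualPart(dec))), 1e-8)

  # sample-permutation equivariance
  perm <- sample(ncol(st))
  stP <- ExpressionStudy(exprMatrix(st)[, perm], studyId = "perm")
  modP <- model
  modP@metagenes <- model@metagenes[, perm]
  decP <- splitExpression(stP, modP)
  expect_equal(projectedPart(decP), projectedPart(dec)[, perm],
               tolerance = 1e-10)
  expect_equal(residualPart(decP), residualPart(dec)[, perm],
               tolerance = 1e-10)
})

test_that("projection is idempotent", {
  st <- randomStudy(35, 14, seed = 6)
  model <- fitSubspace(st, n = 3)
  dec <- splitExpression(st, model)
  x2 <- projectedPart(dec) + rowMeans(exprMatrix(st))
  dimnames(x2) <- dimnames(exprMatrix(st))
  dec2 <- splitExpression(ExpressionStudy(x2, studyId = "proj"), model)
  expect_lt(max(abs(projectedPart(dec2) - projectedPart(dec))), 1e-8)
  rc <- residualPart(dec2) - rowMeans(residualPart(dec2))
  expect_lt(max(abs(rc)), 1e-8)
})

test_that("sample mismatch and rank deficiency are handled", {
  st <- randomStudy(30, 12, seed = 10)
  model <- fitSubspace(st, n = 3)
  st2 <- randomStudy(30, 11, seed = 10)
  expect_error(splitExpression(st2, model), "samples")

  # duplicate metagene rows force rank deficiency
  degen <- model
  degen@metagenes[2, ] <- degen@metagenes[1, ]
  expect_warning(dec <- splitExpression(st, degen), "rank deficient")
  expect_equal(projectedPart(dec) + residualPart(dec), exprMatrix(st),
               tolerance = 1e-10)
})
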