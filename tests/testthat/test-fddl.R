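test_that("soft thresholding has the closed form and solves its prox problem", {
  expect_equal(softThreshold(c(2, -0.3, 0), 0.5), c(1.5, 0, 0))
  v <- c(-2.2, 0.4, 1.7)
  expect_identical(softThreshold(v, 0), v)
  expect_error(softThreshold(v, -0.1), "nonnegative")
  set.seed(2)
  for (i in 1:5) {
    v1 <- rnorm(1, sd = 2); sigma <- runif(1, 0.5, 3); tau <- runif(1, 0, 1.5)
    grid <- seq(-6, 6, by = 1e-4)
    best <- grid[which.min(0.5 * sigma * (grid - v1)^2 + tau * abs(grid))]
    expect_equal(softThreshold(v1, tau / sigma), best, tolerance = 2e-4)
  }
})

test_that("class sub-dictionaries initialise as orthonormal singular bases", {
  set.seed(4)
  d <- makeTinyDataset(nClasses = 2, nGenes = 10, perClass = 5)
  dict <- initDictionary(d, 5)   # full class eigenbasis
  expect_equal(max(abs(sqrt(colSums(dictAtoms(dict)^2)) - 1)), 0,
               tolerance = 1e-10)
  for (i in 1:2) {
    Di <- dictAtoms(dict)[, atomClasses(dict) == i]
    expect_lt(max(abs(crossprod(Di) - diag(ncol(Di)))), 1e-8)
    # full-rank basis reconstructs its class block
    Xi <- exprValues(d)[, sampleLabels(d) == i]
    expect_lt(max(abs(Xi - Di %*% crossprod(Di, Xi))), 1e-8)
  }
  # one-sample class: single atom is the normalised sample
  x <- c(3, 4, 0)
  d1 <- ExpressionDataset(cbind(x, c(1, 0, 0), c(0, 1, 0)), c(1, 2, 2))
  a1 <- dictAtoms(initDictionary(d1, c(1, 1)))[, 1]
  expect_equal(abs(sum(a1 * x / 5)), 1, tolerance = 1e-12)
  expect_error(initDictionary(d1, c(2, 2)), "attainable")
})

test_that("fidelity, scatter and Fisher terms match independent oracles", {
  set.seed(6)
  d <- makeTinyDataset(nClasses = 2, nGenes = 4, perClass = 3)
  dict <- initDictionary(d, 2)
  alphaI <- matrix(rnorm(nAtoms(dict) * 3), nAtoms(dict))
  Xi <- exprValues(d)[, sampleLabels(d) == 1]
  expect_equal(fidelityTerm(Xi, dict, alphaI, 1),
               bruteFidelity(Xi, dictAtoms(dict), atomClasses(dict),
                             alphaI, 1), tolerance = 1e-12)
  # zero coefficients leave twice the block energy
  expect_equal(fidelityTerm(Xi, dict, alphaI * 0, 1), 2 * sum(Xi^2))
  # exact own-class representation with empty cross-blocks vanishes
  code <- matrix(rnorm(2 * 3), 2)
  Di <- dictAtoms(dict)[, atomClasses(dict) == 1]
  a0 <- rbind(code, matrix(0, 2, 3))
  expect_equal(fidelityTerm(Di %*% code, dict, a0, 1), 0, tolerance = 1e-20)

  coef <- matrix(rnorm(4 * 6), 4)
  st <- scatterTraces(coef, sampleLabels(d))
  stO <- bruteScatter(coef, sampleLabels(d))
  expect_equal(st$tr_sw, stO$tr_sw, tolerance = 1e-10)
  expect_equal(st$tr_sb, stO$tr_sb, tolerance = 1e-10)
  same <- coef[, c(1, 1, 1, 1, 1, 1)]
  stSame <- scatterTraces(same, sampleLabels(d))
  expect_equal(stSame$tr_sw, 0)
  expect_equal(stSame$tr_sb, 0)
  # 1-D two-class hand example: columns 0 and 2
  st1 <- scatterTraces(matrix(c(0, 2), 1), c(1, 2))
  expect_equal(st1$tr_sw, 0)
  expect_equal(st1$tr_sb, 2)
  expect_equal(fisherTerm(matrix(c(0, 2), 1), c(1, 2), eta = 1), 2)
  expect_equal(fisherTerm(coef * 0, sampleLabels(d)), 0)
})

test_that("the full objective decomposes into its printed components", {
  set.seed(8)
  d <- makeTinyDataset(nClasses = 3, nGenes = 6, perClass = 3)
  dict <- initDictionary(d, 2)
  coef <- matrix(rnorm(nAtoms(dict) * nSamples(d)), nAtoms(dict))
  pars <- fddlParams(lambda1 = 0.02, lambda2 = 0.3, eta = 0.7)
  y <- sampleLabels(d)
  fid <- sum(vapply(1:3, function(i)
    bruteFidelity(exprValues(d)[, y == i], dictAtoms(dict),
                  atomClasses(dict), coef[, y == i], i), 0))
  stO <- bruteScatter(coef, y)
  expect_equal(fddlObjective(dict, coef, d, pars),
               fid + 0.02 * sum(abs(coef)) +
                 0.3 * (stO$tr_sw - stO$tr_sb) + 0.7 * sum(coef^2),
               tolerance = 1e-10)
  expect_equal(fddlObjective(dict, coef * 0,
                             ExpressionDataset(exprValues(d) * 0, y), pars), 0)
})

test_that("the analytic class gradient agrees with central finite differences", {
  set.seed(10)
  for (rep in 1:20) {
    nc <- sample(2:3, 1)
    d <- makeTinyDataset(nClasses = nc, nGenes = sample(4:10, 1),
                         perClass = sample(2:4, 1), seed = 500 + rep)
    dict <- initDictionary(d, 2)
    coef <- matrix(rnorm(nAtoms(dict) * nSamples(d)), nAtoms(dict))
    pars <- fddlParams(lambda1 = 0.01, lambda2 = runif(1, 0.01, 0.5),
                       eta = runif(1, 0.2, 1.5))
    cls <- sample(nc, 1)
    g <- fddlGradient(cls, dict, coef, d, pars)
    idx <- which(sampleLabels(d) == cls)
    h <- 1e-5
    gfd <- g * 0
    for (r in seq_len(nrow(g))) for (cc in seq_len(ncol(g))) {
      cp <- coef; cp[r, idx[cc]] <- cp[r, idx[cc]] + h
      cm <- coef; cm[r, idx[cc]] <- cm[r, idx[cc]] - h
      gfd[r, cc] <- (fddlQ(cls, dict, cp, d, pars) -
                     fddlQ(cls, dict, cm, d, pars)) / (2 * h)
    }
    expect_lt(max(abs(g - gfd)) / max(abs(gfd)), 1e-5)
  }
})

test_that("ISTA descends its surrogate and reaches subgradient optimality", {
  set.seed(12)
  d <- makeTinyDataset(nClasses = 2, nGenes = 8, perClass = 4)
  dict <- initDictionary(d, 3)
  coef <- matrix(rnorm(nAtoms(dict) * nSamples(d)), nAtoms(dict))
  pars <- fddlParams(lambda1 = 0.05, lambda2 = 0.1,
                     innerIters = 3000L, innerTol = 1e-12)
  upd <- updateCoefficientsClass(1, dict, coef, d, pars)
  expect_true(all(diff(upd$trace) <= 1e-9))
  coef2 <- coef
  coef2[, sampleLabels(d) == 1] <- upd$alpha
  g <- fddlGradient(1, dict, coef2, d, pars)
  A <- upd$alpha
  nz <- A != 0
  expect_lt(max(abs(g[nz] + pars@lambda1 * sign(A[nz]))), 1e-3)
  if (any(!nz)) expect_lt(max(abs(g[!nz])), pars@lambda1 + 1e-3)
})

test_that("a dominant L1 weight zeroes the class block", {
  set.seed(13)
  d <- makeTinyDataset(nClasses = 2, nGenes = 6, perClass = 3)
  dict <- initDictionary(d, 2)
  coef <- matrix(0, nAtoms(dict), nSamples(d))
  g0 <- fddlGradient(1, dict, coef, d, fddlParams(lambda1 = 1e-6))
  big <- fddlParams(lambda1 = 4 * max(abs(g0)))
  upd <- updateCoefficientsClass(1, dict, coef, d, big)
  expect_identical(max(abs(upd$alpha)), 0)
})

test_that("atom-wise dictionary updates keep unit norms and never increase the fit", {
  set.seed(14)
  d <- makeTinyDataset(nClasses = 2, nGenes = 7, perClass = 4)
  dict <- initDictionary(d, 3)
  coef <- matrix(rnorm(nAtoms(dict) * nSamples(d)), nAtoms(dict))
  upd <- updateDictionaryClass(1, dict, coef, d)
  expect_lte(upd$objectiveAfter, upd$objectiveBefore + 1e-10)
  expect_lt(max(abs(sqrt(colSums(dictAtoms(upd$dictionary)^2)) - 1)), 1e-12)
  # single-atom closed form: d = Lambda z^T / ||Lambda z^T||
  d1 <- ExpressionDataset(matrix(rnorm(12), 3), rep(1, 4))
  dict1 <- initDictionary(d1, 1)
  a1 <- matrix(rnorm(4), 1)
  upd1 <- updateDictionaryClass(1, dict1, a1, d1)
  X <- exprValues(d1)
  Lz <- cbind(X, X) %*% c(a1, a1)
  expect_equal(drop(dictAtoms(upd1$dictionary)), drop(Lz / sqrt(sum(Lz^2))),
               tolerance = 1e-12)
  # a dead atom (all-zero coefficient row) is left unchanged with a warning
  coefDead <- coef; coefDead[1, ] <- 0
  expect_warning(updDead <- updateDictionaryClass(1, dict, coefDead, d),
                 "dead atom")
  expect_identical(dictAtoms(updDead$dictionary)[, 1], dictAtoms(dict)[, 1])
})

test_that("the outer objective trace is non-increasing and centers are exact", {
  sim <- simulateClassMeanData(nClasses = 3, nGenes = 20,
                               samplesPerClass = 8, seed = 31)
  fit <- fitFDDL(sim$dataset, fddlParams(lambda1 = 0.01, lambda2 = 0.01))
  tr <- fit@objectiveTrace
  expect_true(all(diff(tr) <= 1e-8 * pmax(1, abs(tr[-length(tr)]))))
  for (i in 1:3) {
    idx <- fit@trainLabels == i
    expect_equal(fit@classCenters[, i],
                 rowMeans(fit@coefficients[, idx]), tolerance = 1e-12)
  }
  expect_lt(max(abs(sqrt(colSums(dictAtoms(fit@dictionary)^2)) - 1)), 1e-10)
  # refits are deterministic
  fit2 <- fitFDDL(sim$dataset, fddlParams(lambda1 = 0.01, lambda2 = 0.01))
  expect_identical(fit@objectiveTrace, fit2@objectiveTrace)
})

test_that("one-class learning with no Fisher term reconstructs generative data", {
  sim <- simulateDictionaryData(nGenes = 20, atomsPerClass = 5, nClasses = 1,
                                samplesPerClass = 30, sparsityK = 2,
                                noiseSd = 0.005, seed = 41)
  fit <- fitFDDL(sim$dataset, fddlParams(lambda1 = 0.01, lambda2 = 0,
                                         eta = 1e-4, outerIters = 15L),
                 atomsPerClass = 5)
  X <- exprValues(sim$dataset)
  rec <- dictAtoms(fit@dictionary) %*% fit@coefficients
  expect_lt(sum((X - rec)^2) / sum(X^2), 0.05)
})

test_that("learned sub-dictionaries recover planted class subspaces", {
  ok <- vapply(1:10, function(s) {
    sim <- simulateDictionaryData(nGenes = 30, atomsPerClass = 3,
                                  nClasses = 3, samplesPerClass = 15,
                                  sparsityK = 3, noiseSd = 0.01,
                                  seed = 600 + s)
    fit <- fitFDDL(sim$dataset, fddlParams(), atomsPerClass = 3)
    all(vapply(1:3, function(i) {
      principalAngleDeg(
        dictAtoms(fit@dictionary)[, atomClasses(fit@dictionary) == i],
        dictAtoms(sim$dictionary)[, atomClasses(sim$dictionary) == i]) < 15
    }, logical(1)))
  }, logical(1))
  expect_gte(sum(ok), 8)
})
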