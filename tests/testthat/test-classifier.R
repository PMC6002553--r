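test_that("SRC coding matches the brute-force oracle and its null threshold", {
  set.seed(24)
  for (i in 1:4) {
    X <- matrix(rnorm(5 * 4), 5)
    X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
    y <- rnorm(5)
    g <- 0.05
    # printed objective ||y - Xa||^2 + g|a|_1 = 2 * (1/2||.||^2 + g/2 |a|_1)
    expect_equal(srcCode(y, X, g), bruteLasso(X, y, g / 2), tolerance = 1e-6)
  }
  X <- matrix(rnorm(10), 5, 2)
  y <- rnorm(5)
  expect_identical(srcCode(y, X, 2 * max(abs(crossprod(X, y))) + 0.01),
                   numeric(2))
  expect_error(srcCode(y, X, -0.1), "nonnegative")
})

test_that("SRC picks the spanning class and breaks ties toward low codes", {
  set.seed(25)
  # class 1 spans the test sample exactly, class 2 is orthogonal noise
  B <- qr.Q(qr(matrix(rnorm(36), 6)))
  X <- cbind(B[, 1:2], B[, 3:4])
  d <- ExpressionDataset(X, c(1, 1, 2, 2))
  y <- 0.8 * B[, 1] - 0.5 * B[, 2]
  expect_identical(srcClassify(y, d, 1e-6), 1L)
  # a coefficient vector forced to zero leaves equal residuals -> class 1
  expect_identical(srcClassify(y, d, 1e6), 1L)
  # y identical to one training column recovers that column
  a <- srcCode(B[, 3], X, 1e-6)
  expect_equal(a[3], 1, tolerance = 1e-4)
  expect_lt(sum((B[, 3] - X %*% a)^2), 1e-8)
})

test_that("local-center scores combine residual and center terms as printed", {
  # identity dictionary, two atoms per class
  dict <- new("StructuredDictionary", atoms = diag(4),
              atomClass = c(1L, 1L, 2L, 2L))
  coefs <- cbind(c(0, 1, 0, 1), c(0, 1, 0, 1), c(1, 0, 1, 0), c(1, 0, 1, 0))
  model <- new("FDDLModel", dictionary = dict, coefficients = coefs,
               classCenters = cbind(c(0, 1, 0, 1), c(1, 0, 1, 0)),
               globalCenter = rowMeans(coefs),
               objectiveTrace = numeric(0), trainLabels = c(1L, 1L, 2L, 2L),
               trainMean = numeric(4), labelNames = c("a", "b"),
               params = fddlParams())
  alpha <- c(1, 0, 1, 0)
  wts <- rep(0.5, 4)
  coding <- new("CodingResult", coefficients = alpha, weights = wts,
                residual = -alpha, nIters = 1L, converged = TRUE,
                stepSizes = numeric(0), deltaTrace = numeric(0),
                muTrace = numeric(0), weightChangeTrace = numeric(0))
  y <- numeric(4)
  # hand evaluation: class residuals ||W^.5 D_i a_i||^2 both 0.5;
  # center distances 4 and 0 -> class 2 for any w > 0
  sc <- localCenterScores(y, coding, model, classifierConfig(w = 0.01))
  expect_equal(sc@residuals, c(0.5, 0.5))
  expect_equal(sc@centerDistances, c(4, 0))
  expect_identical(sc@predicted, 2L)
  # w = 0 scores to pure residuals (tie -> class 1)
  sc0 <- localCenterScores(y, coding, model, classifierConfig(w = 0))
  expect_equal(sc0@scores, sc0@residuals)
  expect_identical(sc0@predicted, 1L)
  # unweighted / power-1 variants follow their printed forms
  sc1 <- localCenterScores(y, coding, model,
                           classifierConfig(w = 0.01,
                                            residualWeighting = "unweighted",
                                            residualPower = 1))
  expect_equal(sc1@residuals, c(1, 1))
  # scores are affine in w with slope = center distance
  sA <- localCenterScores(y, coding, model, classifierConfig(w = 0.2))@scores
  sB <- localCenterScores(y, coding, model, classifierConfig(w = 0.7))@scores
  expect_equal((sB - sA) / 0.5, sc@centerDistances, tolerance = 1e-12)
})

test_that("random-instance scores match a scalar-loop evaluation", {
  set.seed(26)
  sim <- simulateClassMeanData(nClasses = 3, nGenes = 15,
                               samplesPerClass = 5, seed = 27)
  model <- fdrrcFit(sim$dataset, fddlParams(outerIters = 3L))
  y <- exprValues(sim$dataset)[, 1] + rnorm(15, sd = 0.2)
  pr <- fdrrcPredict(y, model, config = classifierConfig(w = 0.05))
  a <- pr$coding@coefficients
  wts <- pr$coding@weights
  D <- dictAtoms(model@dictionary)
  for (i in 1:3) {
    ri <- which(atomClasses(model@dictionary) == i)
    resid <- 0
    for (g in seq_len(15)) {
      rec <- 0
      for (k in ri) rec <- rec + D[g, k] * a[k]
      resid <- resid + wts[g] * (y[g] - rec)^2
    }
    cdist <- sum((a - model@classCenters[, i])^2)
    expect_equal(pr$scores@scores[i], resid + 0.05 * cdist,
                 tolerance = 1e-10)
  }
  expect_identical(pr$label, which.min(pr$scores@scores))
})

test_that("with raw atoms, frozen weights and w = 0 the pipeline is exactly SRC", {
  set.seed(28)
  sim <- simulateClassMeanData(nClasses = 3, nGenes = 20,
                               samplesPerClass = 6, meanShift = 1,
                               seed = 29)
  train <- sim$dataset
  model <- srcDictionaryModel(train)
  gamma <- 0.002
  rp <- robustCodingParams(fixedWeights = TRUE, lambdaCode = gamma / 2)
  cfg <- classifierConfig(w = 0, residualPower = 2)
  agree <- vapply(1:20, function(i) {
    y <- rnorm(20)
    fdrrcPredict(y, model, rp, cfg)$label == srcClassify(y, train, gamma)
  }, logical(1))
  expect_identical(sum(agree), 20L)
})

test_that("prediction is deterministic and survives serialization round trips", {
  sim <- simulateClassMeanData(nClasses = 2, nGenes = 12,
                               samplesPerClass = 6, seed = 33)
  model <- fdrrcFit(sim$dataset, fddlParams(outerIters = 3L))
  set.seed(34)
  Y <- matrix(rnorm(12 * 10), 12)
  p1 <- fdrrcClassify(model, Y)
  p2 <- fdrrcClassify(model, Y)
  expect_identical(p1, p2)
  s1 <- fdrrcPredict(Y[, 1], model)
  s2 <- fdrrcPredict(Y[, 1], model)
  expect_identical(s1$scores@scores, s2$scores@scores)
  path <- withr::local_tempfile(fileext = ".json")
  writeFDDLModel(model, path)
  model2 <- readFDDLModel(path)
  expect_identical(fdrrcClassify(model2, Y), p1)
  expect_equal(fdrrcPredict(Y[, 1], model2)$scores@scores,
               s1$scores@scores, tolerance = 1e-12)
  expect_equal(model2@objectiveTrace, model@objectiveTrace)
})

test_that("labels are invariant to a global positive rescaling in the L1-free configuration", {
  set.seed(36)
  sim <- simulateClassMeanData(nClasses = 2, nGenes = 10,
                               samplesPerClass = 5, seed = 37)
  train <- sim$dataset
  scaled <- ExpressionDataset(exprValues(train) * 7.3,
                              labelNames(train)[sampleLabels(train)])
  rp <- robustCodingParams(fixedWeights = TRUE, lambdaCode = 0)
  cfg <- classifierConfig(w = 0)
  m1 <- srcDictionaryModel(train)
  m2 <- srcDictionaryModel(scaled)
  for (i in 1:10) {
    y <- rnorm(10)
    expect_identical(fdrrcPredict(y, m1, rp, cfg)$label,
                     fdrrcPredict(y * 7.3, m2, rp, cfg)$label)
  }
})

test_that("well-separated classes are recovered on held-out samples", {
  accs <- vapply(1:3, function(s) {
    sim <- simulateClassMeanData(nClasses = 3, nGenes = 50,
                                 samplesPerClass = 15, meanShift = 3,
                                 seed = 900 + s)
    sp <- balanceDivisionSplit(sim$dataset, 10, seed = 950 + s)
    model <- fdrrcFit(sim$dataset[, sp$train], fddlParams())
    pred <- fdrrcClassify(model, exprValues(sim$dataset)[, sp$test])
    mean(pred == sampleLabels(sim$dataset)[sp$test])
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})
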