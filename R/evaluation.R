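#' Balance division split
#'
#' Draws exactly Q training samples per class uniformly at random without
#' replacement; everything else is the test set. Q must leave at least one
#' test sample in every class.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param Q training samples per class.
#' @param seed RNG seed (the split is deterministic per seed).
#' @return list with integer index vectors \code{train} and \code{test},
#'   plus \code{Q} and \code{seed}
#' @export
balanceDivisionSplit <- function(dataset, Q, seed = NULL) {
  stopifnot(is(dataset, "ExpressionDataset"))
  sz <- classSizes(dataset)
  if (Q < 1L || Q > min(sz) - 1L) {
    lim <- which.min(sz)
    stop(sprintf(
      "Q = %d out of range: class '%s' has %d samples, so Q must lie in [1, %d]",
      Q, labelNames(dataset)[lim], sz[lim], min(sz) - 1L))
  }
  lab <- sampleLabels(dataset)
  train <- .withSeed(seed, {
    unlist(lapply(seq_len(classCount(dataset)), function(i) {
      idx <- which(lab == i)
      sort(idx[sample.int(length(idx), Q)])
    }))
  })
  list(train = sort(train), test = setdiff(seq_along(lab), train),
       Q = as.integer(Q), seed = seed)
}

#' Stratified k-fold partition
#'
#' Shuffles each class and deals it over the k folds so per-class counts
#' across folds differ by at most one; the classes' leftover samples are
#' rotated over the folds so total fold sizes also stay within one of each
#' other.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param k number of folds (<= number of samples).
#' @param seed RNG seed.
#' @return list of k split plans, each with \code{train}, \code{test} and
#'   \code{fold}
#' @export
stratifiedKFold <- function(dataset, k = 10L, seed = NULL) {
  stopifnot(is(dataset, "ExpressionDataset"))
  n <- nSamples(dataset)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  if (k < 2L) stop("k must be at least 2")
  lab <- sampleLabels(dataset)
  folds <- vector("list", k)
  offset <- 0L
  .withSeed(seed, {
    for (i in seq_len(classCount(dataset))) {
      idx <- which(lab == i)
      idx <- idx[sample.int(length(idx))]
      assign <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], idx[assign == f])
      offset <- (offset + length(idx)) %% k
    }
  })
  lapply(seq_len(k), function(f)
    list(train = sort(setdiff(seq_len(n), folds[[f]])),
         test = sort(folds[[f]]), fold = f))
}

#' Accuracy, sensitivity and specificity (percent)
#'
#' Accuracy is the percentage of correct predictions. For a binary problem
#' with an explicit positive class, sensitivity = TP/(TP+FN) and
#' specificity = TN/(TN+FP), both in percent. With
#' \code{positiveClass = "macro"} both are macro-averaged one-vs-rest over
#' the classes present in the true labels (the convention used for
#' multi-class data).
#'
#' @param trueLabels,predictedLabels integer class codes of equal length.
#' @param positiveClass class code treated as positive, or \code{"macro"}.
#' @return list with \code{accuracy}, \code{sensitivity},
#'   \code{specificity} (percent) and the \code{confusion} matrix (rows =
#'   true classes)
#' @export
computeMetrics <- function(trueLabels, predictedLabels,
                           positiveClass = "macro") {
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors must have equal length")
  cc <- max(trueLabels, predictedLabels)
  conf <- matrix(0L, cc, cc,
                 dimnames = list(true = seq_len(cc), pred = seq_len(cc)))
  for (i in seq_along(trueLabels))
    conf[trueLabels[i], predictedLabels[i]] <-
      conf[trueLabels[i], predictedLabels[i]] + 1L
  acc <- 100 * sum(diag(conf)) / length(trueLabels)
  oneVsRest <- function(pos) {
    tp <- conf[pos, pos]
    fn <- sum(conf[pos, ]) - tp
    fp <- sum(conf[, pos]) - tp
    tn <- sum(conf) - tp - fn - fp
    c(sens = 100 * tp / (tp + fn),
      spec = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
  }
  if (identical(positiveClass, "macro")) {
    present <- sort(unique(trueLabels))
    sv <- vapply(present, oneVsRest, numeric(2))
    sens <- mean(sv["sens", ])
    spec <- mean(sv["spec", ], na.rm = TRUE)
  } else {
    if (!positiveClass %in% trueLabels)
      stop("positive class ", positiveClass,
           " is absent from the true labels; sensitivity is undefined")
    sv <- oneVsRest(positiveClass)
    sens <- sv["sens"]; spec <- sv["spec"]
  }
  list(accuracy = acc, sensitivity = unname(sens),
       specificity = unname(spec), confusion = conf)
}

#' Hyperparameter grid search by stratified cross-validation
#'
#' Exhaustively evaluates every (lambda1, lambda2, w) triple by k-fold
#' stratified CV accuracy of the full pipeline (fit, robust-code, classify)
#' and returns the argmax; ties go to the lexicographically smallest
#' triple. The default grids are the standard small search sets. Coding is
#' shared across the w grid, since the decision scores are affine in w.
#'
#' @param train training [ExpressionDataset-class].
#' @param lambda1Grid,lambda2Grid,wGrid numeric candidate vectors.
#' @param folds number of CV folds; reduced with a warning when the
#'   smallest class has fewer samples.
#' @param seed RNG seed for the fold partition.
#' @param atomsPerClass passed to [fitFDDL()].
#' @param rparams a [RobustCodingParams-class].
#' @param fddlTemplate an [FDDLParams-class] supplying everything except
#'   lambda1/lambda2.
#' @return list with \code{best} (named list lambda1, lambda2, w),
#'   \code{bestAccuracy}, and \code{table} (one row per grid point)
#' @export
gridSearch <- function(train,
                       lambda1Grid = c(0.001, 0.005, 0.01, 0.05, 0.1),
                       lambda2Grid = c(0.001, 0.005, 0.01, 0.05, 0.1),
                       wGrid = c(0.0001, 0.0005, 0.001, 0.005, 0.01,
                                 0.05, 0.1),
                       folds = 5L, seed = NULL, atomsPerClass = "auto",
                       rparams = robustCodingParams(),
                       fddlTemplate = fddlParams()) {
  stopifnot(is(train, "ExpressionDataset"))
  if (!length(lambda1Grid) || !length(lambda2Grid) || !length(wGrid))
    stop("grids must be nonempty")
  minSz <- min(classSizes(train))
  if (minSz < folds) {
    warning("smallest class has ", minSz, " samples; reducing folds from ",
            folds, " to ", minSz, call. = FALSE)
    folds <- minSz
  }
  plans <- stratifiedKFold(train, folds, seed)
  lambda1Grid <- sort(lambda1Grid)
  lambda2Grid <- sort(lambda2Grid)
  wGrid <- sort(wGrid)
  grid <- expand.grid(w = wGrid, lambda2 = lambda2Grid,
                      lambda1 = lambda1Grid)[, c("lambda1", "lambda2", "w")]
  total <- 0L
  hits <- array(0, dim = c(length(lambda1Grid), length(lambda2Grid),
                           length(wGrid)))
  for (plan in plans) {
    tr <- train[, plan$train]
    teX <- exprValues(train)[, plan$test, drop = FALSE]
    teY <- sampleLabels(train)[plan$test]
    total <- total + length(teY)
    for (i1 in seq_along(lambda1Grid)) for (i2 in seq_along(lambda2Grid)) {
      pars <- fddlParams(lambda1 = lambda1Grid[i1],
                         lambda2 = lambda2Grid[i2],
                         eta = fddlTemplate@eta, sigma = fddlTemplate@sigma,
                         innerIters = fddlTemplate@innerIters,
                         outerIters = fddlTemplate@outerIters,
                         tol = fddlTemplate@tol,
                         innerTol = fddlTemplate@innerTol)
      model <- fitFDDL(tr, pars, atomsPerClass)
      for (j in seq_len(ncol(teX))) {
        coding <- ir3cCode(teX[, j], model@dictionary, rparams,
                           model@trainMean)
        for (iw in seq_along(wGrid)) {
          sc <- localCenterScores(teX[, j], coding, model,
                                  classifierConfig(w = wGrid[iw]))
          if (sc@predicted == teY[j])
            hits[i1, i2, iw] <- hits[i1, i2, iw] + 1
        }
      }
    }
  }
  tab <- grid
  tab$accuracy <- NA_real_
  for (r in seq_len(nrow(grid))) {
    i1 <- match(grid$lambda1[r], lambda1Grid)
    i2 <- match(grid$lambda2[r], lambda2Grid)
    iw <- match(grid$w[r], wGrid)
    tab$accuracy[r] <- 100 * hits[i1, i2, iw] / total
  }
  ord <- order(tab$lambda1, tab$lambda2, tab$w)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  best <- tab[which.max(tab$accuracy), ]
  list(best = list(lambda1 = best$lambda1, lambda2 = best$lambda2,
                   w = best$w),
       bestAccuracy = best$accuracy, table = tab)
}

#' Balance-division evaluation protocol
#'
#' For each Q and repeat: draw a balanced split, compute ReliefF weights on
#' the training partition only, keep the top genes, fit the model on the
#' reduced training set, robust-code and classify the test samples over the
#' same gene subset, and score. Reported metrics are means over repeats.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param QValues integer vector of training-set sizes per class.
#' @param repeats splits per Q (default 10).
#' @param topGenes genes kept after ReliefF ranking (default 400; clipped
#'   to the gene count).
#' @param seed master seed; per-repeat split seeds are derived from it.
#' @param fddl an [FDDLParams-class].
#' @param rparams a [RobustCodingParams-class].
#' @param config a [ClassifierConfig-class].
#' @param kNeighbors ReliefF neighbour count.
#' @return list with \code{perRepeat} (one row per Q x repeat),
#'   \code{summary} (means per Q), \code{selectedGenes} (list of gene-id
#'   vectors per Q x repeat) and \code{splits} (the split plans used, for
#'   auditing that only training indices informed selection and fitting)
#' @export
runBDMExperiment <- function(dataset, QValues, repeats = 10L,
                             topGenes = 400L, seed = NULL,
                             fddl = fddlParams(),
                             rparams = robustCodingParams(),
                             config = classifierConfig(),
                             kNeighbors = 10L) {
  stopifnot(is(dataset, "ExpressionDataset"))
  splitSeeds <- .withSeed(seed,
    sample.int(.Machine$integer.max - 1L, length(QValues) * repeats))
  rows <- list()
  genes <- list()
  plans <- list()
  k <- 0L
  for (qi in seq_along(QValues)) {
    Q <- QValues[qi]
    for (r in seq_len(repeats)) {
      k <- k + 1L
      plan <- balanceDivisionSplit(dataset, Q, splitSeeds[k])
      plans[[k]] <- plan
      trainSet <- dataset[, plan$train]
      gw <- relieffWeights(trainSet, kNeighbors = kNeighbors)
      nk <- min(topGenes, nGenes(dataset))
      sel <- gw@ranking[seq_len(nk)]
      trainSel <- trainSet[sel, ]
      model <- fdrrcFit(trainSel, fddl)
      teX <- exprValues(dataset)[sel, plan$test, drop = FALSE]
      teY <- sampleLabels(dataset)[plan$test]
      pred <- fdrrcClassify(model, teX, rparams, config)
      met <- computeMetrics(teY, pred)
      rows[[k]] <- data.frame(Q = Q, rep = r, accuracy = met$accuracy,
                              sensitivity = met$sensitivity,
                              specificity = met$specificity)
      genes[[k]] <- geneIds(dataset)[sel]
    }
  }
  perRepeat <- do.call(rbind, rows)
  agg <- stats::aggregate(perRepeat[c("accuracy", "sensitivity",
                                      "specificity")],
                          by = list(Q = perRepeat$Q), FUN = mean)
  list(perRepeat = perRepeat, summary = agg, selectedGenes = genes,
       splits = plans)
}
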