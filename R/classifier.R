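#' Sparse code a test sample over a sample dictionary (SRC baseline)
#'
#' Solves \eqn{\min_\alpha \|y - X\alpha\|_2^2 + \gamma\|\alpha\|_1} to
#' subgradient optimality. Columns of X are expected to be L2-normalised
#' (as [srcClassify()] arranges).
#'
#' @param y test gene vector.
#' @param X dictionary of training samples (genes x samples).
#' @param gamma L1 weight, a small positive constant.
#' @return coefficient vector
#' @export
srcCode <- function(y, X, gamma) {
  if (gamma < 0) stop("gamma must be nonnegative")
  # the printed objective has no 1/2 on the fit term; fold the factor 2 into
  # the equivalent 1/2-scaled problem so one solver serves both
  .lassoCD(as.matrix(X), y, gamma / 2)
}

#' Sparse representation classification (SRC) of one test sample
#'
#' Codes the sample over the L2-normalised training samples, then assigns
#' the class whose own samples reconstruct it with minimal squared error
#' \eqn{e_i = \|y - X_i \hat\alpha_i\|_2^2}; ties go to the lowest class
#' code.
#'
#' @param y test gene vector.
#' @param train training [ExpressionDataset-class].
#' @param gamma L1 weight (default 0.001).
#' @return predicted integer class code
#' @export
srcClassify <- function(y, train, gamma = 0.001) {
  stopifnot(is(train, "ExpressionDataset"))
  X <- exprValues(train)
  nrm <- sqrt(colSums(X^2))
  nrm[nrm == 0] <- 1
  Xn <- sweep(X, 2L, nrm, "/")
  alpha <- srcCode(y, Xn, gamma)
  lab <- sampleLabels(train)
  errs <- vapply(seq_len(classCount(train)), function(i) {
    idx <- lab == i
    sum((y - Xn[, idx, drop = FALSE] %*% alpha[idx])^2)
  }, numeric(1))
  which.min(errs)
}

#' Local-center decision scores
#'
#' For each class, combines a class-restricted reconstruction residual with
#' the squared distance of the full code to that class's coefficient
#' center:
#' \deqn{e_i = \|W^{1/2}(y - D_i \hat\alpha_i)\|_2^{\,power} +
#'   w\,\|\hat\alpha - m_i\|_2^2}
#' with W the robust coder's final weights (or identity under
#' \code{"unweighted"}). The predicted class is the argmin, ties broken by
#' lowest code.
#'
#' @param y test gene vector.
#' @param coding a [CodingResult-class] computed against
#'   \code{model@dictionary}.
#' @param model an [FDDLModel-class].
#' @param config a [ClassifierConfig-class].
#' @return a [ClassScores-class]
#' @export
localCenterScores <- function(y, coding, model,
                              config = classifierConfig()) {
  stopifnot(is(coding, "CodingResult"), is(model, "FDDLModel"))
  dict <- model@dictionary
  cc <- classCount(dict)
  if (ncol(model@classCenters) < cc)
    stop("model is missing class centers")
  D <- dictAtoms(dict)
  alpha <- coding@coefficients
  wts <- if (config@residualWeighting == "final_weights") coding@weights
         else rep(1, length(y))
  res <- cd <- numeric(cc)
  for (i in seq_len(cc)) {
    ri <- .atomIdx(dict, i)
    resid <- y - D[, ri, drop = FALSE] %*% alpha[ri]
    res[i] <- sqrt(sum(wts * resid^2))^config@residualPower
    cd[i] <- sum((alpha - model@classCenters[, i])^2)
  }
  scores <- res + config@w * cd
  new("ClassScores", scores = scores, predicted = which.min(scores),
      residuals = res, centerDistances = cd, labelNames = model@labelNames)
}

#' Classify one test sample with the full robust-coding pipeline
#'
#' Runs the iteratively reweighted robust coder against the learned
#' dictionary, then applies the local-center rule.
#'
#' @param y test gene vector.
#' @param model an [FDDLModel-class].
#' @param rparams a [RobustCodingParams-class].
#' @param config a [ClassifierConfig-class].
#' @return list with \code{label} (integer code), \code{labelName},
#'   \code{scores} ([ClassScores-class]) and \code{coding}
#'   ([CodingResult-class])
#' @export
fdrrcPredict <- function(y, model, rparams = robustCodingParams(),
                         config = classifierConfig()) {
  stopifnot(is(model, "FDDLModel"))
  if (length(y) != nrow(dictAtoms(model@dictionary)))
    stop("gene dimension of the test sample does not match the model")
  coding <- ir3cCode(y, model@dictionary, rparams, model@trainMean)
  sc <- localCenterScores(y, coding, model, config)
  list(label = sc@predicted,
       labelName = model@labelNames[sc@predicted],
       scores = sc, coding = coding)
}

#' Classify the columns of a test matrix
#'
#' @param model an [FDDLModel-class].
#' @param newdata genes x samples matrix over the model's gene set.
#' @param rparams,config see [fdrrcPredict()].
#' @return integer vector of predicted class codes
#' @export
fdrrcClassify <- function(model, newdata,
                          rparams = robustCodingParams(),
                          config = classifierConfig()) {
  newdata <- as.matrix(newdata)
  vapply(seq_len(ncol(newdata)), function(j)
    fdrrcPredict(newdata[, j], model, rparams, config)$label, integer(1))
}

#' Fit the FDRRC model
#'
#' Thin composition of [fitFDDL()]: the class centers are the means of the
#' final training coefficients per class.
#'
#' @inheritParams fitFDDL
#' @return an [FDDLModel-class]
#' @export
fdrrcFit <- function(train, params = fddlParams(), atomsPerClass = "auto",
                     seed = NULL) {
  fitFDDL(train, params, atomsPerClass, seed)
}

#' Model with the raw normalised training samples as dictionary
#'
#' Builds an [FDDLModel-class] whose atoms are the L2-normalised training
#' samples themselves (no dictionary learning), with zero coefficients and
#' centers. With frozen identity weights, w = 0 and squared residuals, the
#' robust-coding pipeline over this model reduces exactly to the SRC
#' baseline (note the penalty scaling: the SRC objective carries no 1/2 on
#' its fit term, so \code{lambdaCode = gamma / 2} matches the two solvers).
#'
#' @param train training [ExpressionDataset-class].
#' @return an [FDDLModel-class]
#' @export
srcDictionaryModel <- function(train) {
  stopifnot(is(train, "ExpressionDataset"))
  X <- exprValues(train)
  nrm <- sqrt(colSums(X^2))
  if (any(nrm == 0)) stop("training samples must be nonzero")
  dict <- new("StructuredDictionary", atoms = sweep(X, 2L, nrm, "/"),
              atomClass = sampleLabels(train))
  p <- ncol(X)
  new("FDDLModel", dictionary = dict,
      coefficients = matrix(0, p, p),
      classCenters = matrix(0, p, classCount(train)),
      globalCenter = numeric(p),
      objectiveTrace = numeric(0),
      trainLabels = sampleLabels(train),
      trainMean = rowMeans(X),
      labelNames = labelNames(train),
      params = fddlParams())
}
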