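#' Discriminative data fidelity term for one class
#'
#' \deqn{r(X_i, D, \alpha_i) = \|X_i - D\alpha_i\|_F^2 +
#'   \|X_i - D_i \alpha_i^i\|_F^2 + \sum_{j \ne i} \|D_j \alpha_i^j\|_F^2}
#' so a class block should be reconstructed by the whole dictionary and by
#' its own sub-dictionary, while the other sub-dictionaries contribute
#' nothing.
#'
#' @param Xi class sample block (genes x n_i).
#' @param dict a [StructuredDictionary-class].
#' @param alphaI coefficient block for the class's samples (p x n_i).
#' @param classId the class the block belongs to.
#' @return nonnegative scalar
#' @export
fidelityTerm <- function(Xi, dict, alphaI, classId) {
  cc <- classCount(dict)
  if (classId < 1L || classId > cc) stop("class index out of range")
  D <- dictAtoms(dict)
  val <- sum((Xi - D %*% alphaI)^2)
  for (j in seq_len(cc)) {
    rj <- .atomIdx(dict, j)
    recj <- D[, rj, drop = FALSE] %*% alphaI[rj, , drop = FALSE]
    val <- val + if (j == classId) sum((Xi - recj)^2) else sum(recj^2)
  }
  val
}

#' Within- and between-class scatter traces of a coefficient matrix
#'
#' \code{tr_sw} sums squared distances of each column to its class mean;
#' \code{tr_sb} sums \eqn{n_i \|m_i - m\|_2^2} over classes, with m the
#' global column mean.
#'
#' @param coef p x n coefficient matrix.
#' @param labels integer class codes per column.
#' @return list with numeric elements \code{tr_sw} and \code{tr_sb}
#' @export
scatterTraces <- function(coef, labels) {
  coef <- as.matrix(coef)
  if (ncol(coef) != length(labels))
    stop("one label per coefficient column is required")
  m <- rowMeans(coef)
  sw <- 0; sb <- 0
  for (i in unique(labels)) {
    block <- coef[, labels == i, drop = FALSE]
    mi <- rowMeans(block)
    sw <- sw + sum((block - mi)^2)
    sb <- sb + ncol(block) * sum((mi - m)^2)
  }
  list(tr_sw = sw, tr_sb = sb)
}

#' Fisher discrimination term on the coefficients
#'
#' \eqn{tr(S_W) - tr(S_B) + \eta \|\alpha\|_F^2}; may be negative when the
#' elastic weight is small.
#'
#' @param coef p x n coefficient matrix.
#' @param labels class codes per column.
#' @param eta elastic weight (default 1).
#' @return scalar
#' @export
fisherTerm <- function(coef, labels, eta = 1) {
  st <- scatterTraces(coef, labels)
  st$tr_sw - st$tr_sb + eta * sum(coef^2)
}

#' Full dictionary-learning objective
#'
#' Sum of the class fidelity terms, the L1 penalty, the Fisher scatter
#' difference weighted by lambda2, and a single elastic term weighted by
#' eta:
#' \deqn{\sum_i r(X_i, D, \alpha_i) + \lambda_1\|\alpha\|_1 +
#'   \lambda_2(tr S_W - tr S_B) + \eta\|\alpha\|_F^2}
#'
#' @param dict a [StructuredDictionary-class].
#' @param coef p x n coefficient matrix.
#' @param train the training [ExpressionDataset-class].
#' @param params an [FDDLParams-class].
#' @return scalar
#' @export
fddlObjective <- function(dict, coef, train, params) {
  X <- exprValues(train)
  y <- sampleLabels(train)
  val <- 0
  for (i in seq_len(classCount(train)))
    val <- val + fidelityTerm(X[, y == i, drop = FALSE], dict,
                              coef[, y == i, drop = FALSE], i)
  st <- scatterTraces(coef, y)
  val + params@lambda1 * sum(abs(coef)) +
    params@lambda2 * (st$tr_sw - st$tr_sb) + params@eta * sum(coef^2)
}

# Smooth part Q of the per-class problem: fidelity + lambda2 * (scatter part
# restricted to alpha_i, with the class and global means taken as linear
# functions of alpha_i) + eta ||alpha_i||_F^2. `fixedSum` is the row sum of
# the other classes' coefficient columns, `mOther` the per-class means of
# the fixed blocks.
.classQ <- function(A, Xi, dict, classId, lambda2, eta, fixedSum, nTotal,
                    mOther, nPerClass) {
  ni <- ncol(A)
  mi <- rowMeans(A)
  mg <- (fixedSum + mi * ni) / nTotal
  sw <- sum((A - mi)^2)
  sb <- nPerClass[classId] * sum((mi - mg)^2)
  for (k in seq_along(nPerClass)) if (k != classId)
    sb <- sb + nPerClass[k] * sum((mOther[, k] - mg)^2)
  fidelityTerm(Xi, dict, A, classId) + lambda2 * (sw - sb) + eta * sum(A^2)
}

.classQGrad <- function(A, Xi, dict, classId, lambda2, eta, fixedSum,
                        nTotal, nPerClass) {
  D <- dictAtoms(dict)
  cc <- classCount(dict)
  g <- 2 * crossprod(D, D %*% A - Xi)
  for (j in seq_len(cc)) {
    rj <- .atomIdx(dict, j)
    Aj <- A[rj, , drop = FALSE]
    Dj <- D[, rj, drop = FALSE]
    g[rj, ] <- g[rj, ] +
      if (j == classId) 2 * crossprod(Dj, Dj %*% Aj - Xi) else
        2 * crossprod(Dj, Dj %*% Aj)
  }
  ni <- ncol(A)
  mi <- rowMeans(A)
  mg <- (fixedSum + mi * ni) / nTotal
  # d/dA [ ||A - M_i||_F^2 ] = 2 (A - M_i); the between-class part collapses
  # to -2 (m_i - m) 1^T because the prior-weighted mean deviations sum to 0
  g + lambda2 * (2 * (A - mi) - 2 * outer(mi - mg, rep(1, ni))) + 2 * eta * A
}

# Hessian-vector product of .classQ (Q is quadratic, so this is exact and
# obtained as the linear part of the gradient).
.classQHv <- function(V, dict, classId, lambda2, eta, nTotal) {
  D <- dictAtoms(dict)
  cc <- classCount(dict)
  h <- 2 * crossprod(D, D %*% V)
  for (j in seq_len(cc)) {
    rj <- .atomIdx(dict, j)
    Dj <- D[, rj, drop = FALSE]
    h[rj, ] <- h[rj, ] + 2 * crossprod(Dj, Dj %*% V[rj, , drop = FALSE])
  }
  ni <- ncol(V)
  vi <- rowMeans(V)
  vg <- vi * ni / nTotal
  h + lambda2 * (2 * (V - vi) - 2 * outer(vi - vg, rep(1, ni))) +
    2 * eta * V
}

# spectral norm of the per-class Hessian by power iteration (deterministic
# start), inflated by 5% as a safety margin for the ISTA majorisation
.classCurvature <- function(dict, classId, lambda2, eta, ni, nTotal) {
  p <- nAtoms(dict)
  V <- matrix(sin(seq_len(p * ni)) + 1.1, p, ni)
  V <- V / sqrt(sum(V^2))
  lam <- 0
  for (it in seq_len(60L)) {
    HV <- .classQHv(V, dict, classId, lambda2, eta, nTotal)
    nrm <- sqrt(sum(HV^2))
    if (nrm < 1e-300) break
    lamNew <- nrm
    V <- HV / nrm
    if (it > 5L && abs(lamNew - lam) <= 1e-8 * lamNew) { lam <- lamNew; break }
    lam <- lamNew
  }
  max(lam, 1e-12) * 1.05
}

#' Gradient of the smooth per-class objective
#'
#' Analytic gradient of Q (fidelity + weighted Fisher part + elastic term)
#' with respect to the class coefficient block, taking the class and global
#' coefficient means as linear functions of the block. Exposed for
#' finite-difference verification.
#'
#' @param classId class whose block is differentiated.
#' @param dict a [StructuredDictionary-class].
#' @param coef full p x n coefficient matrix (other classes held fixed).
#' @param train the training [ExpressionDataset-class].
#' @param params an [FDDLParams-class].
#' @return p x n_i gradient matrix
#' @export
fddlGradient <- function(classId, dict, coef, train, params) {
  pre <- .classContext(classId, dict, coef, train)
  .classQGrad(pre$A, pre$Xi, dict, classId, params@lambda2, params@eta,
              pre$fixedSum, pre$nTotal, pre$nPerClass)
}

#' Smooth per-class objective Q
#'
#' Companion of [fddlGradient()]: the value of the smooth part of the
#' per-class coefficient problem at the current block.
#'
#' @inheritParams fddlGradient
#' @return scalar
#' @export
fddlQ <- function(classId, dict, coef, train, params) {
  pre <- .classContext(classId, dict, coef, train)
  .classQ(pre$A, pre$Xi, dict, classId, params@lambda2, params@eta,
          pre$fixedSum, pre$nTotal, pre$mOther, pre$nPerClass)
}

.classContext <- function(classId, dict, coef, train) {
  X <- exprValues(train)
  y <- sampleLabels(train)
  if (classId < 1L || classId > classCount(train))
    stop("class index out of range")
  idx <- which(y == classId)
  cc <- classCount(train)
  nPerClass <- tabulate(y, cc)
  mOther <- matrix(0, nrow(coef), cc)
  for (k in seq_len(cc)) if (k != classId)
    mOther[, k] <- rowMeans(coef[, y == k, drop = FALSE])
  list(A = coef[, idx, drop = FALSE],
       Xi = X[, idx, drop = FALSE],
       fixedSum = rowSums(coef[, -idx, drop = FALSE]),
       nTotal = ncol(X), nPerClass = nPerClass, mOther = mOther)
}

#' ISTA update of one class's coefficient block
#'
#' Proximal-gradient (ISTA) steps on \eqn{Q(\alpha_i) + 2\tau\|\alpha_i\|_1}
#' with \eqn{\tau = \lambda_1/2}: each step takes a gradient move of length
#' \eqn{1/(2\sigma)} followed by soft thresholding at \eqn{\tau/\sigma}.
#' With sigma at least half the largest Hessian eigenvalue (the auto
#' default) the objective is non-increasing across steps. The block is
#' warm-started from its current value in \code{coef}.
#'
#' @inheritParams fddlGradient
#' @return list with \code{alpha} (updated p x n_i block), \code{trace}
#'   (objective after each step, starting value first) and \code{sigma}
#'   (curvature constant used)
#' @export
updateCoefficientsClass <- function(classId, dict, coef, train, params) {
  pre <- .classContext(classId, dict, coef, train)
  lam2 <- params@lambda2; eta <- params@eta
  sigma <- params@sigma
  if (is.na(sigma))
    sigma <- .classCurvature(dict, classId, lam2, eta, ncol(pre$A),
                             pre$nTotal) / 2
  thr <- params@lambda1 / (2 * sigma)
  A <- pre$A
  evalF <- function(B)
    .classQ(B, pre$Xi, dict, classId, lam2, eta, pre$fixedSum, pre$nTotal,
            pre$mOther, pre$nPerClass) + params@lambda1 * sum(abs(B))
  trace <- evalF(A)
  for (h in seq_len(params@innerIters)) {
    g <- .classQGrad(A, pre$Xi, dict, classId, lam2, eta, pre$fixedSum,
                     pre$nTotal, pre$nPerClass)
    if (!all(is.finite(g)))
      stop("non-finite gradient in class ", classId,
           ": check the scaling of the input data")
    Anew <- softThreshold(A - g / (2 * sigma), thr)
    trace <- c(trace, evalF(Anew))
    move <- sqrt(sum((Anew - A)^2))
    A <- Anew
    if (move <= params@innerTol * max(sqrt(sum(A^2)), 1e-12)) break
  }
  list(alpha = A, trace = trace, sigma = sigma)
}

#' Fit the Fisher discrimination dictionary learning model
#'
#' Alternates per-class ISTA coefficient updates (warm-started) with
#' atom-wise closed-form dictionary updates until the relative change of
#' the objective falls below \code{tol} or \code{outerIters} alternations
#' are done. Classes are swept in ascending code order. The recorded
#' objective trace is non-increasing because every sub-step descends the
#' global objective.
#'
#' @param train an [ExpressionDataset-class] with at least 2 samples.
#' @param params an [FDDLParams-class].
#' @param atomsPerClass per-class atom count or "auto" (see
#'   [initDictionary()]).
#' @param seed unused (the fit is deterministic); accepted for interface
#'   uniformity.
#' @return an [FDDLModel-class]
#' @examples
#' sim <- simulateClassMeanData(nClasses = 2, nGenes = 20,
#'                              samplesPerClass = 6, seed = 1)
#' fit <- fitFDDL(sim$dataset, fddlParams(outerIters = 3))
#' fit
#' @export
fitFDDL <- function(train, params = fddlParams(), atomsPerClass = "auto",
                    seed = NULL) {
  stopifnot(is(train, "ExpressionDataset"))
  if (nSamples(train) < 2L) stop("at least two training samples are needed")
  y <- sampleLabels(train)
  cc <- classCount(train)
  dict <- initDictionary(train, atomsPerClass)
  coef <- matrix(0, nAtoms(dict), nSamples(train))
  trace <- fddlObjective(dict, coef, train, params)
  for (outer in seq_len(params@outerIters)) {
    for (i in seq_len(cc)) {
      upd <- updateCoefficientsClass(i, dict, coef, train, params)
      coef[, y == i] <- upd$alpha
    }
    for (i in seq_len(cc)) {
      upd <- updateDictionaryClass(i, dict, coef, train)
      dict <- upd$dictionary
    }
    obj <- fddlObjective(dict, coef, train, params)
    if (!is.finite(obj))
      stop("objective became non-finite at outer iteration ", outer)
    trace <- c(trace, obj)
    if (abs(trace[outer] - obj) <= params@tol * max(1, abs(trace[outer])))
      break
  }
  centers <- vapply(seq_len(cc), function(i)
    rowMeans(coef[, y == i, drop = FALSE]), numeric(nAtoms(dict)))
  centers <- matrix(centers, nrow = nAtoms(dict))
  new("FDDLModel", dictionary = dict, coefficients = coef,
      classCenters = centers, globalCenter = rowMeans(coef),
      objectiveTrace = trace, trainLabels = y,
      trainMean = rowMeans(exprValues(train)),
      labelNames = labelNames(train), params = params)
}
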