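#' Demarcation point of the logistic residual weight
#'
#' Returns the phi-th order statistic of the squared residuals, with phi
#' the largest integer strictly smaller than tau * m (clamped to
#' \code{[1, m]}). The default ascending sorting makes delta the
#' tau-quantile: the fraction tau of genes with the smallest squared
#' residuals (the presumed inliers) sit below the demarcation point and
#' receive weight above one half, while the top 1 - tau fraction is
#' down-weighted. Some presentations state the phi-th \emph{largest}
#' element instead; taken literally that places the demarcation near the
#' (1 - tau) quantile and down-weights almost every gene, inverting the
#' inlier fraction the parameter tau is meant to control, so that variant
#' is exposed only as \code{sorting = "descending"}.
#'
#' @param squaredResiduals nonnegative vector of squared per-gene residuals.
#' @param tau quantile fraction in (0, 1).
#' @param sorting order statistic direction; "ascending" (default, the
#'   tau-quantile) or "descending" (the literal phi-th largest).
#' @return positive scalar
#' @examples
#' estimateDelta(c(1, 4, 9, 16), 0.9)  # 3rd smallest = 9
#' estimateDelta(c(1, 4, 9, 16), 0.9, sorting = "descending")  # 3rd largest = 4
#' @export
estimateDelta <- function(squaredResiduals, tau = 0.9,
                          sorting = c("ascending", "descending")) {
  sorting <- match.arg(sorting)
  m <- length(squaredResiduals)
  if (m < 2L) stop("at least two residuals are required")
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  if (any(squaredResiduals < 0)) stop("squared residuals must be nonnegative")
  f <- tau * m
  phi <- if (floor(f) == f) as.integer(f) - 1L else as.integer(floor(f))
  phi <- min(max(phi, 1L), m)
  delta <- sort(squaredResiduals, decreasing = sorting == "descending")[phi]
  if (delta <= 0) {
    if (all(squaredResiduals == 0))
      warning("all residuals are zero (degenerate perfect fit); ",
              "delta floored at machine epsilon", call. = FALSE)
    delta <- .Machine$double.eps
  }
  delta
}

#' Logistic residual weight
#'
#' \deqn{\omega(e) = \frac{\exp(-\mu e^2 + \mu\delta)}
#'   {1 + \exp(-\mu e^2 + \mu\delta)}}
#' evaluated overflow-safely: strictly decreasing in \eqn{e^2}, exactly 0.5
#' at \eqn{e^2 = \delta}, and clamped away from exact 0 and 1.
#'
#' @param e residual (vectorised).
#' @param mu positive decay rate.
#' @param delta positive demarcation point.
#' @return weights in the open interval (0, 1)
#' @export
weightFunction <- function(e, mu, delta) {
  if (mu <= 0 || delta <= 0) stop("mu and delta must be positive")
  .logistic(-mu * e^2 + mu * delta)
}

#' Residual loss implied by the logistic weight
#'
#' \deqn{\rho(e) = -\frac{1}{2\mu}\left[\ln(1 + e^{-\mu e^2 + \mu\delta})
#'   - \ln(1 + e^{\mu\delta})\right]}
#' An even, nondecreasing-in-\eqn{|e|} loss with \eqn{\rho(0) = 0} whose
#' derivative satisfies \eqn{\rho'(e) = e\,\omega(e)}, tying the weight
#' matrix to a genuine M-estimation loss.
#'
#' @inheritParams weightFunction
#' @return loss values (vectorised over e)
#' @export
rhoTheta <- function(e, mu, delta) {
  if (mu <= 0 || delta <= 0) stop("mu and delta must be positive")
  -(.log1pexp(-mu * e^2 + mu * delta) - .log1pexp(mu * delta)) / (2 * mu)
}

#' Weighted L1-regularised sparse coding
#'
#' Solves \eqn{\min_\alpha \frac12 \|W^{1/2}(y - D\alpha)\|_2^2 +
#' \lambda\|\alpha\|_1} for a diagonal nonnegative weight vector by cyclic
#' coordinate descent on the row-scaled problem, to subgradient optimality.
#' A gene with weight zero drops out of the fit entirely.
#'
#' @param y gene vector.
#' @param dict a [StructuredDictionary-class] or a plain atom matrix.
#' @param weights nonnegative per-gene weights (diagonal of W).
#' @param lambda L1 weight (>= 0).
#' @param beta sparsity exponent; only 1 is supported.
#' @param init optional warm-start coefficients (the solution is
#'   independent of the start; this only saves iterations).
#' @return coefficient vector (one per atom)
#' @export
weightedSparseCode <- function(y, dict, weights, lambda, beta = 1,
                               init = NULL) {
  if (beta != 1) stop("only beta = 1 is supported")
  if (lambda < 0) stop("lambda must be nonnegative")
  D <- if (is(dict, "StructuredDictionary")) dictAtoms(dict) else as.matrix(dict)
  if (length(weights) == 1L) weights <- rep(weights, length(y))
  if (any(weights < 0)) stop("weights must be nonnegative")
  sw <- sqrt(weights)
  .lassoCD(D * sw, y * sw, lambda, init = init)
}

#' Backtracking line search over a geometric step grid
#'
#' Returns the largest step in \{1, 1/2, 1/4, ..., 2^-10\} for which the
#' objective at \code{alphaPrev + step * (alphaStar - alphaPrev)} does not
#' exceed the objective at \code{alphaPrev}; trial points with non-finite
#' objective are skipped. Falls back to the grid minimum with a warning when
#' no step qualifies.
#'
#' @param alphaPrev current coefficients.
#' @param alphaStar target coefficients.
#' @param objective function mapping a coefficient vector to a scalar.
#' @return step size in (0, 1]
#' @export
lineSearchStep <- function(alphaPrev, alphaStar, objective) {
  base <- objective(alphaPrev)
  if (!is.finite(base)) stop("objective is not finite at the current point")
  dir <- alphaStar - alphaPrev
  for (k in 0:10) {
    step <- 2^(-k)
    val <- objective(alphaPrev + step * dir)
    if (is.finite(val) && val <= base) return(step)
  }
  warning("no step on the grid decreased the objective; using 2^-10",
          call. = FALSE)
  2^(-10)
}

#' Iteratively reweighted robust coding of a test sample
#'
#' Codes \code{y} against the dictionary while re-estimating a per-gene
#' diagonal weight each iteration: the residual of the current
#' reconstruction sets the demarcation point \eqn{\delta} (order statistic
#' at fraction tau), the rate \eqn{\mu = s/\delta}, and logistic weights;
#' a weighted L1 coding step then proposes new coefficients, blended with
#' the previous ones by a backtracking line search on the robust objective
#' \eqn{\sum_i \rho(e_i) + \lambda\|\alpha\|_1}. Iteration stops when the
#' relative change of the weight vector falls below phi.
#'
#' Outlier genes — large-magnitude corruptions the Gaussian residual model
#' cannot absorb — end with weights near 0 and are effectively excluded
#' from the fit; clean genes end near 1.
#'
#' @param y gene vector (length matching the dictionary rows).
#' @param dict a [StructuredDictionary-class].
#' @param params a [RobustCodingParams-class].
#' @param meanTrain per-gene mean of the training samples, used as the
#'   initial reconstruction when \code{init = "mean"}.
#' @return a [CodingResult-class]
#' @export
ir3cCode <- function(y, dict, params = robustCodingParams(),
                     meanTrain = NULL) {
  D <- dictAtoms(dict)
  m <- nrow(D)
  if (length(y) != m)
    stop("test sample has ", length(y), " genes but the dictionary has ", m)
  if (params@fixedWeights) {
    w <- rep(1 - .Machine$double.eps / 2, m)
    alpha <- weightedSparseCode(y, D, rep(1, m), params@lambdaCode)
    return(new("CodingResult", coefficients = alpha, weights = w,
               residual = drop(y - D %*% alpha), nIters = 1L,
               converged = TRUE, stepSizes = numeric(0),
               deltaTrace = numeric(0), muTrace = numeric(0),
               weightChangeTrace = numeric(0)))
  }
  if (params@init == "mean") {
    if (is.null(meanTrain))
      stop("init = 'mean' requires the training gene-mean vector")
    recon <- meanTrain
    alpha <- NULL
  } else {
    alpha <- rep(1 / m, ncol(D))
    recon <- drop(D %*% alpha)
  }
  wPrev <- NULL
  steps <- deltas <- mus <- wchg <- numeric(0)
  converged <- FALSE
  t <- 0L
  while (t < params@maxIters) {
    t <- t + 1L
    e <- y - recon
    delta <- estimateDelta(e^2, params@tau)
    mu <- params@s / delta
    w <- weightFunction(e, mu, delta)
    deltas <- c(deltas, delta); mus <- c(mus, mu)
    if (!is.null(wPrev)) {
      stat <- .l2(w - wPrev) / .l2(wPrev)
      wchg <- c(wchg, stat)
      if (is.finite(stat) && stat < params@phi) {
        wPrev <- w
        converged <- TRUE
        break
      }
    }
    alphaStar <- weightedSparseCode(y, D, w, params@lambdaCode,
                                    init = alpha)
    if (is.null(alpha)) {
      alpha <- alphaStar
    } else {
      robustObj <- function(a)
        sum(rhoTheta(y - drop(D %*% a), mu, delta)) +
          params@lambdaCode * sum(abs(a))
      step <- lineSearchStep(alpha, alphaStar, robustObj)
      steps <- c(steps, step)
      alpha <- alpha + step * (alphaStar - alpha)
    }
    recon <- drop(D %*% alpha)
    wPrev <- w
  }
  new("CodingResult", coefficients = alpha, weights = wPrev,
      residual = drop(y - D %*% alpha), nIters = t, converged = converged,
      stepSizes = steps, deltaTrace = deltas, muTrace = mus,
      weightChangeTrace = wchg)
}
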