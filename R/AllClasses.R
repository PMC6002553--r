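#' @import methods
NULL

#' ExpressionDataset: a labelled gene-expression matrix
#'
#' Canonical container for all downstream computation: a numeric matrix of
#' expression values in genes x samples orientation, one integer class code
#' per sample (contiguous in \code{1..c}, encoded by first appearance of the
#' original labels), plus gene and sample identifiers.
#'
#' @slot values numeric matrix, genes in rows, samples in columns; all entries
#'   finite.
#' @slot labels integer vector of class codes, one per sample, in \code{1..c};
#'   every class has at least one sample.
#' @slot labelNames character vector of length \code{c} giving the original
#'   label for each class code.
#' @slot geneIds character vector of gene identifiers (one per row).
#' @slot sampleIds character vector of sample identifiers (one per column).
#'
#' @seealso [ExpressionDataset()], [readExpressionDataset()]
#' @export
setClass("ExpressionDataset",
  representation(
    values    = "matrix",
    labels    = "integer",
    labelNames = "character",
    geneIds   = "character",
    sampleIds = "character"
  )
)

setValidity("ExpressionDataset", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (length(v) && !all(is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)[1L, ]
    return(sprintf("non-finite value at gene row %d, sample column %d",
                   bad[1L], bad[2L]))
  }
  if (length(object@labels) != ncol(v))
    return("one label per sample column is required")
  if (length(object@geneIds) != nrow(v))
    return("one gene id per row is required")
  if (length(object@sampleIds) != ncol(v))
    return("one sample id per column is required")
  c <- length(object@labelNames)
  if (ncol(v) > 0L) {
    if (any(object@labels < 1L) || any(object@labels > c))
      return("labels must be contiguous class codes in 1..c")
    if (!all(seq_len(c) %in% object@labels))
      return("every class code in 1..c must occur at least once")
  }
  TRUE
})

#' GeneWeights: ReliefF relevance scores and ranking
#'
#' @slot weights numeric relevance score per gene (dimensionless, in
#'   \eqn{[-1, 1]} for range-normalised differences).
#' @slot ranking integer permutation of gene indices by descending weight,
#'   ties broken by ascending gene index.
#' @slot geneIds character, gene identifiers aligned with \code{weights}.
#' @export
setClass("GeneWeights",
  representation(weights = "numeric", ranking = "integer",
                 geneIds = "character")
)

setValidity("GeneWeights", function(object) {
  m <- length(object@weights)
  if (length(object@ranking) != m)
    return("ranking length must equal weight count")
  if (m && !identical(sort(object@ranking), seq_len(m)))
    return("ranking must be a permutation of 1..m")
  if (length(object@geneIds) != m)
    return("one gene id per weight is required")
  TRUE
})

#' StructuredDictionary: unit-norm atoms partitioned by class
#'
#' @slot atoms numeric matrix (genes x atoms); every column has unit L2 norm.
#' @slot atomClass integer class code per atom; every class owns at least one
#'   atom.
#' @export
setClass("StructuredDictionary",
  representation(atoms = "matrix", atomClass = "integer")
)

setValidity("StructuredDictionary", function(object) {
  if (ncol(object@atoms) != length(object@atomClass))
    return("one class code per atom is required")
  if (ncol(object@atoms) == 0L) return("dictionary must have at least one atom")
  nrm <- sqrt(colSums(object@atoms^2))
  if (any(abs(nrm - 1) > 1e-8))
    return(sprintf("atom %d is not unit-norm (|norm - 1| = %.3g)",
                   which.max(abs(nrm - 1)), max(abs(nrm - 1))))
  c <- max(object@atomClass)
  if (!all(seq_len(c) %in% object@atomClass))
    return("every class in 1..c must own at least one atom")
  TRUE
})

#' FDDLParams: hyperparameters of Fisher discrimination dictionary learning
#'
#' @slot lambda1 L1 sparsity weight (> 0).
#' @slot lambda2 Fisher discrimination weight (> 0).
#' @slot eta elastic (Frobenius) weight on the coefficients, applied once in
#'   the global objective (>= 0).
#' @slot sigma ISTA curvature constant; \code{NA} means auto-estimate per
#'   class from the largest Hessian eigenvalue so descent is guaranteed.
#' @slot innerIters maximum ISTA steps per class update.
#' @slot outerIters maximum alternations between coefficient and dictionary
#'   updates.
#' @slot tol relative objective-change stopping threshold for the outer loop.
#' @slot innerTol relative coefficient-change stopping threshold for ISTA.
#' @export
setClass("FDDLParams",
  representation(lambda1 = "numeric", lambda2 = "numeric", eta = "numeric",
                 sigma = "numeric", innerIters = "integer",
                 outerIters = "integer", tol = "numeric", innerTol = "numeric")
)

setValidity("FDDLParams", function(object) {
  if (object@lambda1 < 0) return("lambda1 must be >= 0")
  if (object@lambda2 < 0) return("lambda2 must be >= 0")
  if (object@eta < 0) return("eta must be >= 0")
  if (object@tol <= 0) return("tol must be > 0")
  if (object@innerIters < 1L || object@outerIters < 1L)
    return("iteration counts must be positive")
  TRUE
})

#' FDDLModel: learned structured dictionary plus training-coefficient geometry
#'
#' @slot dictionary the learned [StructuredDictionary-class].
#' @slot coefficients p x n matrix of training sparse codes (rows follow the
#'   dictionary atoms, columns the training samples).
#' @slot classCenters p x c matrix; column i is the local center m_i, the mean
#'   coefficient vector of class-i training samples.
#' @slot globalCenter mean coefficient vector over all training samples.
#' @slot objectiveTrace value of the learning objective after initialisation
#'   and after each outer alternation.
#' @slot trainLabels integer class codes of the training samples.
#' @slot trainMean per-gene mean of the training expression values (used to
#'   initialise the robust coder's reconstruction).
#' @slot labelNames original class labels, for reporting predictions.
#' @slot params the [FDDLParams-class] the model was fitted with.
#' @export
setClass("FDDLModel",
  representation(dictionary = "StructuredDictionary",
                 coefficients = "matrix",
                 classCenters = "matrix",
                 globalCenter = "numeric",
                 objectiveTrace = "numeric",
                 trainLabels = "integer",
                 trainMean = "numeric",
                 labelNames = "character",
                 params = "FDDLParams")
)

setValidity("FDDLModel", function(object) {
  p <- ncol(object@dictionary@atoms)
  if (nrow(object@coefficients) != p)
    return("coefficient rows must match atom count")
  cc <- max(object@dictionary@atomClass)
  if (ncol(object@classCenters) != cc)
    return("one center column per class is required")
  if (length(object@trainLabels) != ncol(object@coefficients))
    return("one training label per coefficient column is required")
  for (i in seq_len(cc)) {
    idx <- which(object@trainLabels == i)
    if (length(idx)) {
      mi <- rowMeans(object@coefficients[, idx, drop = FALSE])
      if (max(abs(mi - object@classCenters[, i])) > 1e-10)
        return(sprintf("center %d is not the mean of its class coefficients", i))
    }
  }
  if (length(object@objectiveTrace) && !all(is.finite(object@objectiveTrace)))
    return("objective trace must be finite")
  TRUE
})

#' RobustCodingParams: scalars of the iteratively reweighted robust coder
#'
#' @slot tau residual quantile fraction locating the demarcation point
#'   (default 0.9).
#' @slot s logistic sharpness constant; mu is recomputed each iteration as
#'   s / delta (default 8).
#' @slot lambdaCode L1 weight of the weighted coding stage (>= 0).
#' @slot beta sparsity exponent of the coefficient prior; only beta = 1 is
#'   solved.
#' @slot phi convergence threshold on the relative change of the weight
#'   vector.
#' @slot maxIters iteration cap.
#' @slot init reconstruction initialisation, \code{"mean"} (training gene
#'   means) or \code{"uniform"} (all coefficients 1/m).
#' @slot fixedWeights when TRUE the weights stay frozen at identity and a
#'   single coding pass is performed (reduces the coder to a plain LASSO).
#' @export
setClass("RobustCodingParams",
  representation(tau = "numeric", s = "numeric", lambdaCode = "numeric",
                 beta = "numeric", phi = "numeric", maxIters = "integer",
                 init = "character", fixedWeights = "logical")
)

setValidity("RobustCodingParams", function(object) {
  if (object@tau <= 0 || object@tau >= 1) return("tau must lie in (0, 1)")
  if (object@s <= 0) return("s must be > 0")
  if (object@lambdaCode < 0) return("lambdaCode must be >= 0")
  if (object@phi <= 0) return("phi must be > 0")
  if (object@maxIters < 1L) return("maxIters must be positive")
  if (!object@init %in% c("mean", "uniform"))
    return("init must be 'mean' or 'uniform'")
  if (object@beta != 1) return("only beta = 1 is supported")
  TRUE
})

#' CodingResult: output of the iteratively reweighted robust coder
#'
#' @slot coefficients final sparse code over the dictionary atoms.
#' @slot weights final per-gene diagonal weights, strictly inside (0, 1).
#' @slot residual per-gene residual y - D alpha at the returned coefficients.
#' @slot nIters iterations performed.
#' @slot converged TRUE when the weight-change criterion was met.
#' @slot stepSizes accepted line-search step per iteration (after the first).
#' @slot deltaTrace demarcation point per iteration.
#' @slot muTrace logistic rate per iteration.
#' @slot weightChangeTrace relative weight-change statistic per iteration.
#' @export
setClass("CodingResult",
  representation(coefficients = "numeric", weights = "numeric",
                 residual = "numeric", nIters = "integer",
                 converged = "logical", stepSizes = "numeric",
                 deltaTrace = "numeric", muTrace = "numeric",
                 weightChangeTrace = "numeric")
)

setValidity("CodingResult", function(object) {
  if (any(object@weights <= 0) || any(object@weights >= 1))
    return("weights must lie strictly in (0, 1)")
  TRUE
})

#' ClassifierConfig: the local-center decision rule's knobs
#'
#' @slot w balance between the class-wise residual and the
#'   coefficient-to-center distance (>= 0).
#' @slot residualWeighting \code{"final_weights"} applies the robust coder's
#'   final diagonal weights inside the residual norm; \code{"unweighted"} uses
#'   the plain residual.
#' @slot residualPower power applied to the weighted residual norm, 1 or 2.
#' @export
setClass("ClassifierConfig",
  representation(w = "numeric", residualWeighting = "character",
                 residualPower = "numeric")
)

setValidity("ClassifierConfig", function(object) {
  if (object@w < 0) return("w must be >= 0")
  if (!object@residualWeighting %in% c("final_weights", "unweighted"))
    return("residualWeighting must be 'final_weights' or 'unweighted'")
  if (!object@residualPower %in% c(1, 2))
    return("residualPower must be 1 or 2")
  TRUE
})

#' ClassScores: per-class decision scores for one test sample
#'
#' @slot scores combined score per class (lower is better).
#' @slot predicted argmin class code, ties broken by lowest index.
#' @slot residuals class-wise residual component per class.
#' @slot centerDistances squared distance of the code to each class center.
#' @slot labelNames original class labels.
#' @export
setClass("ClassScores",
  representation(scores = "numeric", predicted = "integer",
                 residuals = "numeric", centerDistances = "numeric",
                 labelNames = "character")
)
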