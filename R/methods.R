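#' Construct an ExpressionDataset
#'
#' Labels of any atomic type are re-encoded to contiguous integer codes
#' \code{1..c} in order of first appearance; the original labels are kept in
#' \code{labelNames}.
#'
#' @param values numeric matrix, genes in rows and samples in columns.
#' @param labels vector of class labels, one per sample column.
#' @param geneIds optional gene identifiers; defaults to rownames or
#'   \code{gene1..geneM}.
#' @param sampleIds optional sample identifiers; defaults to colnames or
#'   \code{sample1..sampleN}.
#' @return an [ExpressionDataset-class]
#' @examples
#' d <- ExpressionDataset(matrix(rnorm(12), 3, 4), c("A", "A", "B", "B"))
#' classSizes(d)
#' @export
ExpressionDataset <- function(values, labels, geneIds = NULL,
                              sampleIds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(labels) != ncol(values))
    stop("label count (", length(labels), ") does not match sample count (",
         ncol(values), ")")
  lev <- unique(labels)
  codes <- match(labels, lev)
  if (is.null(geneIds))
    geneIds <- if (!is.null(rownames(values))) rownames(values) else
      paste0("gene", seq_len(nrow(values)))
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(colnames(values))) colnames(values) else
      paste0("sample", seq_len(ncol(values)))
  dimnames(values) <- NULL
  new("ExpressionDataset", values = values, labels = as.integer(codes),
      labelNames = as.character(lev), geneIds = as.character(geneIds),
      sampleIds = as.character(sampleIds))
}

#' @rdname ExpressionDataset-class
#' @aliases nGenes,ExpressionDataset-method
#' @export
setMethod("nGenes", "ExpressionDataset", function(x) nrow(x@values))

#' @rdname ExpressionDataset-class
#' @export
setMethod("nSamples", "ExpressionDataset", function(x) ncol(x@values))

#' @rdname ExpressionDataset-class
#' @export
setMethod("classCount", "ExpressionDataset",
          function(x) length(x@labelNames))

#' @rdname ExpressionDataset-class
#' @export
setMethod("exprValues", "ExpressionDataset", function(x) x@values)

#' @rdname ExpressionDataset-class
#' @export
setMethod("sampleLabels", "ExpressionDataset", function(x) x@labels)

#' @rdname ExpressionDataset-class
#' @export
setMethod("labelNames", "ExpressionDataset", function(x) x@labelNames)

#' @rdname ExpressionDataset-class
#' @export
setMethod("geneIds", "ExpressionDataset", function(x) x@geneIds)

#' @rdname ExpressionDataset-class
#' @export
setMethod("sampleIds", "ExpressionDataset", function(x) x@sampleIds)

#' @rdname ExpressionDataset-class
#' @export
setMethod("classSizes", "ExpressionDataset", function(x)
  tabulate(x@labels, nbins = classCount(x)))

#' Subset an ExpressionDataset by genes and/or samples
#'
#' Class codes are preserved (not re-encoded); a subset that drops a class
#' entirely fails validity, since every downstream consumer assumes
#' contiguous codes with non-empty classes.
#'
#' @param x an [ExpressionDataset-class]
#' @param i gene (row) index
#' @param j sample (column) index
#' @param ... ignored
#' @param drop ignored (always FALSE)
#' @export
setMethod("[", "ExpressionDataset", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  new("ExpressionDataset",
      values = x@values[i, j, drop = FALSE],
      labels = x@labels[j],
      labelNames = x@labelNames,
      geneIds = x@geneIds[i],
      sampleIds = x@sampleIds[j])
})

setMethod("show", "ExpressionDataset", function(object) {
  cat("ExpressionDataset:", nGenes(object), "genes x", nSamples(object),
      "samples,", classCount(object), "classes\n")
  sz <- classSizes(object)
  cat("  classes:",
      paste0(object@labelNames, " (n=", sz, ")", collapse = ", "), "\n")
})

#' @rdname StructuredDictionary-class
#' @export
setMethod("dictAtoms", "StructuredDictionary", function(x) x@atoms)

#' @rdname StructuredDictionary-class
#' @export
setMethod("atomClasses", "StructuredDictionary", function(x) x@atomClass)

#' @rdname StructuredDictionary-class
#' @export
setMethod("nAtoms", "StructuredDictionary", function(x) ncol(x@atoms))

#' @rdname StructuredDictionary-class
#' @export
setMethod("classCount", "StructuredDictionary",
          function(x) max(x@atomClass))

setMethod("show", "StructuredDictionary", function(object) {
  cat("StructuredDictionary:", nrow(object@atoms), "genes x",
      ncol(object@atoms), "atoms,", max(object@atomClass), "classes\n")
  cat("  atoms per class:",
      paste(tabulate(object@atomClass), collapse = ", "), "\n")
})

setMethod("show", "FDDLModel", function(object) {
  cat("FDDLModel\n")
  show(object@dictionary)
  cat("  training samples:", ncol(object@coefficients), "\n")
  tr <- object@objectiveTrace
  if (length(tr))
    cat(sprintf("  objective: %.6g -> %.6g (%d outer iterations)\n",
                tr[1L], tr[length(tr)], length(tr) - 1L))
})

setMethod("show", "CodingResult", function(object) {
  cat(sprintf(
    "CodingResult: %d atoms, %d/%d nonzero; %d iterations (%s)\n",
    length(object@coefficients), sum(object@coefficients != 0),
    length(object@coefficients), object@nIters,
    if (object@converged) "converged" else "iteration cap reached"))
  cat(sprintf("  residual L2 %.4g; %d/%d genes with weight > 0.5\n",
              sqrt(sum(object@residual^2)), sum(object@weights > 0.5),
              length(object@weights)))
})

setMethod("show", "GeneWeights", function(object) {
  cat("GeneWeights:", length(object@weights), "genes; top 5:",
      paste(object@geneIds[object@ranking[seq_len(min(5, length(object@ranking)))]],
            collapse = ", "), "\n")
})

#' Hyperparameters for Fisher discrimination dictionary learning
#'
#' Defaults take the sparsity and discrimination weights from the middle of
#' the standard search grid \{0.001, 0.005, 0.01, 0.05, 0.1\}, the elastic
#' weight eta = 1, and auto-estimate the ISTA curvature constant.
#'
#' @param lambda1 L1 sparsity weight.
#' @param lambda2 Fisher discrimination weight.
#' @param eta elastic Frobenius weight on the coefficients.
#' @param sigma ISTA curvature constant; NA = auto (largest Hessian
#'   eigenvalue of the smooth objective, guaranteeing descent).
#' @param innerIters,outerIters iteration caps for the ISTA inner loop and
#'   the outer alternation.
#' @param tol relative objective-change threshold for the outer loop.
#' @param innerTol relative coefficient-change threshold for ISTA.
#' @return an [FDDLParams-class]
#' @export
fddlParams <- function(lambda1 = 0.005, lambda2 = 0.01, eta = 1,
                       sigma = NA_real_, innerIters = 50L, outerIters = 10L,
                       tol = 1e-4, innerTol = 1e-6) {
  new("FDDLParams", lambda1 = lambda1, lambda2 = lambda2, eta = eta,
      sigma = as.numeric(sigma), innerIters = as.integer(innerIters),
      outerIters = as.integer(outerIters), tol = tol, innerTol = innerTol)
}

#' Parameters of the iteratively reweighted robust coder
#'
#' tau = 0.9 and s = 8 are the tumor-classification settings; mu is
#' recomputed every iteration as s / delta with delta the tau-quantile order
#' statistic of the squared residuals.
#'
#' @param tau residual quantile fraction in (0, 1).
#' @param s logistic sharpness constant.
#' @param lambdaCode L1 weight of the coding stage.
#' @param beta coefficient-prior exponent; only 1 is supported.
#' @param phi convergence threshold on relative weight change.
#' @param maxIters iteration cap.
#' @param init reconstruction initialisation: "mean" (training gene means) or
#'   "uniform" (all coefficients equal to 1/m).
#' @param fixedWeights freeze the weights at identity (single plain-LASSO
#'   pass); used for baseline reductions.
#' @return a [RobustCodingParams-class]
#' @export
robustCodingParams <- function(tau = 0.9, s = 8, lambdaCode = 0.001,
                               beta = 1, phi = 1e-3, maxIters = 100L,
                               init = c("mean", "uniform"),
                               fixedWeights = FALSE) {
  new("RobustCodingParams", tau = tau, s = s, lambdaCode = lambdaCode,
      beta = beta, phi = phi, maxIters = as.integer(maxIters),
      init = match.arg(init), fixedWeights = isTRUE(fixedWeights))
}

#' Configuration of the local-center decision rule
#'
#' The default combines the robustly weighted class residual (squared) with
#' the squared distance of the code to each class center, balanced by w.
#'
#' @param w balance weight (>= 0).
#' @param residualWeighting "final_weights" or "unweighted".
#' @param residualPower 1 or 2.
#' @return a [ClassifierConfig-class]
#' @export
classifierConfig <- function(w = 0.001,
                             residualWeighting = c("final_weights",
                                                   "unweighted"),
                             residualPower = 2) {
  new("ClassifierConfig", w = w,
      residualWeighting = match.arg(residualWeighting),
      residualPower = residualPower)
}
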