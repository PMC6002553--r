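#' Serialize a fitted model to JSON
#'
#' Writes every slot of the model (atoms, atom classes, training
#' coefficients, centers, hyperparameters, objective trace) to a single
#' portable JSON file at full double precision, so that
#' \code{readFDDLModel(writeFDDLModel(m, f))} predicts identically to m.
#'
#' @param model an [FDDLModel-class].
#' @param path output path.
#' @return invisibly, the path
#' @export
writeFDDLModel <- function(model, path) {
  stopifnot(is(model, "FDDLModel"))
  p <- model@params
  obj <- list(
    format = "fdrrc-model",
    version = 1L,
    atoms = model@dictionary@atoms,
    atomClass = model@dictionary@atomClass,
    coefficients = model@coefficients,
    classCenters = model@classCenters,
    globalCenter = model@globalCenter,
    objectiveTrace = model@objectiveTrace,
    trainLabels = model@trainLabels,
    trainMean = model@trainMean,
    labelNames = model@labelNames,
    params = list(lambda1 = p@lambda1, lambda2 = p@lambda2, eta = p@eta,
                  sigma = p@sigma, innerIters = p@innerIters,
                  outerIters = p@outerIters, tol = p@tol,
                  innerTol = p@innerTol)
  )
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              matrix = "rowmajor", na = "null"), path)
  invisible(path)
}

#' Load a model written by [writeFDDLModel()]
#'
#' @param path path to the JSON file.
#' @return an [FDDLModel-class]
#' @export
readFDDLModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "fdrrc-model"))
    stop("not a serialized model: ", path)
  pp <- obj$params
  sigma <- if (is.null(pp$sigma)) NA_real_ else as.numeric(pp$sigma)
  params <- fddlParams(lambda1 = pp$lambda1, lambda2 = pp$lambda2,
                       eta = pp$eta, sigma = sigma,
                       innerIters = pp$innerIters,
                       outerIters = pp$outerIters, tol = pp$tol,
                       innerTol = pp$innerTol)
  dict <- new("StructuredDictionary", atoms = as.matrix(obj$atoms),
              atomClass = as.integer(obj$atomClass))
  new("FDDLModel", dictionary = dict,
      coefficients = as.matrix(obj$coefficients),
      classCenters = as.matrix(obj$classCenters),
      globalCenter = as.numeric(obj$globalCenter),
      objectiveTrace = as.numeric(obj$objectiveTrace),
      trainLabels = as.integer(obj$trainLabels),
      trainMean = as.numeric(obj$trainMean),
      labelNames = as.character(obj$labelNames),
      params = params)
}
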