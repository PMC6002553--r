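#' @describeIn ExpressionDataset-class number of genes (rows)
#' @param x an object
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @describeIn ExpressionDataset-class number of samples (columns)
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @describeIn ExpressionDataset-class number of classes c
#' @export
setGeneric("classCount", function(x) standardGeneric("classCount"))

#' @describeIn ExpressionDataset-class the genes x samples value matrix
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @describeIn ExpressionDataset-class integer class codes per sample
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @describeIn ExpressionDataset-class original label per class code
#' @export
setGeneric("labelNames", function(x) standardGeneric("labelNames"))

#' @describeIn ExpressionDataset-class gene identifiers
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @describeIn ExpressionDataset-class sample identifiers
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @describeIn ExpressionDataset-class per-class sample counts n_i
#' @export
setGeneric("classSizes", function(x) standardGeneric("classSizes"))

#' @describeIn StructuredDictionary-class the genes x atoms matrix
#' @param x an object
#' @export
setGeneric("dictAtoms", function(x) standardGeneric("dictAtoms"))

#' @describeIn StructuredDictionary-class class code per atom
#' @export
setGeneric("atomClasses", function(x) standardGeneric("atomClasses"))

#' @describeIn StructuredDictionary-class total atom count p
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
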