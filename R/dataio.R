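.delimFor <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, tsv = "\t", csv = ",",
         stop("unsupported extension '.", ext, "': use .tsv or .csv"))
}

#' Read an expression matrix and its labels from delimited text
#'
#' The matrix file carries a header row of sample ids and a first column of
#' gene ids (delimiter by extension: .tsv tab, .csv comma). The label file
#' has two columns, sample id and class label, with a header. Sample ids in
#' the label file must be a permutation of the matrix sample ids; labels are
#' matched by id, then re-encoded to contiguous codes by first appearance in
#' matrix column order.
#'
#' @param matrixPath path to the matrix file.
#' @param labelsPath path to the two-column label file.
#' @param orientation whether genes or samples are the rows of the physical
#'   file; the returned dataset is always genes x samples.
#' @return an [ExpressionDataset-class]
#' @export
readExpressionDataset <- function(matrixPath, labelsPath,
                                  orientation = c("genes_in_rows",
                                                  "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(matrixPath)) stop("matrix file not found: ", matrixPath)
  if (!file.exists(labelsPath)) stop("label file not found: ", labelsPath)
  raw <- utils::read.table(matrixPath, header = TRUE,
                           sep = .delimFor(matrixPath), check.names = FALSE,
                           row.names = 1, colClasses = "character",
                           comment.char = "")
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw)), nrow(raw), ncol(raw)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-numeric or missing cell at row '%s' (%d), column '%s' (%d)",
      rownames(raw)[bad[1L]], bad[1L], colnames(raw)[bad[2L]], bad[2L]))
  }
  dimnames(vals) <- dimnames(raw)
  if (orientation == "samples_in_rows") vals <- t(vals)
  lab <- utils::read.table(labelsPath, header = TRUE,
                           sep = .delimFor(labelsPath), check.names = FALSE,
                           colClasses = "character", comment.char = "")
  if (ncol(lab) < 2L)
    stop("label file must have two columns: sample id, class label")
  if (nrow(lab) != ncol(vals))
    stop("label count (", nrow(lab), ") does not match sample count (",
         ncol(vals), ")")
  ord <- match(colnames(vals), lab[[1L]])
  if (anyNA(ord))
    stop("sample ids in the label file do not match the matrix: missing '",
         colnames(vals)[which(is.na(ord))[1L]], "'")
  ExpressionDataset(vals, lab[[2L]][ord], geneIds = rownames(vals),
                    sampleIds = colnames(vals))
}

#' Write an expression dataset as delimited text
#'
#' Values are written with enough significant digits for a lossless
#' round-trip through [readExpressionDataset()] (relative error below
#' 1e-12); labels are written as the original label strings.
#'
#' @param dataset an [ExpressionDataset-class]
#' @param matrixPath,labelsPath output paths (.tsv or .csv).
#' @return invisibly, the dataset
#' @export
writeExpressionDataset <- function(dataset, matrixPath, labelsPath) {
  stopifnot(is(dataset, "ExpressionDataset"))
  for (p in c(matrixPath, labelsPath)) {
    d <- dirname(p)
    if (!dir.exists(d)) stop("directory does not exist: ", d)
  }
  v <- exprValues(dataset)
  out <- data.frame(gene_id = geneIds(dataset),
                    format(v, digits = 17, trim = TRUE, scientific = TRUE),
                    check.names = FALSE)
  colnames(out) <- c("gene_id", sampleIds(dataset))
  ok <- try(utils::write.table(out, matrixPath, sep = .delimFor(matrixPath),
                               quote = FALSE, row.names = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write matrix file: ", matrixPath)
  lab <- data.frame(sample_id = sampleIds(dataset),
                    label = labelNames(dataset)[sampleLabels(dataset)])
  utils::write.table(lab, labelsPath, sep = .delimFor(labelsPath),
                     quote = FALSE, row.names = FALSE)
  invisible(dataset)
}
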