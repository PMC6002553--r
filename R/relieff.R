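#' ReliefF gene weights
#'
#' Multi-class ReliefF over the training set: every instance contributes the
#' mean per-gene difference to its k nearest misses in each other class
#' (weighted by the class prior P(class)/(1 - P(own))) minus the mean
#' difference to its k nearest hits. Differences are normalised per gene by
#' the training range, so weights lie in \eqn{[-1, 1]}; a gene that is
#' constant over the training set receives weight exactly 0. By default all
#' instances are visited in order, which makes the result deterministic
#' irrespective of the seed; a random subsample of instances can be requested
#' via \code{nSampleIterations}.
#'
#' @param train an [ExpressionDataset-class] with at least two classes.
#' @param kNeighbors nearest hits/misses per class; clipped per class when a
#'   class has fewer samples.
#' @param nSampleIterations number of instances to visit; NULL (default)
#'   visits all.
#' @param seed RNG seed, used only when subsampling instances.
#' @return a [GeneWeights-class]
#' @export
relieffWeights <- function(train, kNeighbors = 10L,
                           nSampleIterations = NULL, seed = NULL) {
  stopifnot(is(train, "ExpressionDataset"))
  if (classCount(train) < 2L)
    stop("ReliefF needs at least two classes (misses are undefined)")
  X <- exprValues(train)
  y <- sampleLabels(train)
  n <- ncol(X)
  m <- nrow(X)
  rng <- apply(X, 1L, function(r) diff(range(r)))
  live <- rng > 0
  Xn <- X
  Xn[live, ] <- (X[live, ] - apply(X[live, , drop = FALSE], 1L, min)) /
    rng[live]
  Xn[!live, ] <- 0
  # Manhattan distance on range-normalised values = summed per-gene diff
  Dm <- as.matrix(stats::dist(t(Xn), method = "manhattan"))
  prior <- tabulate(y, classCount(train)) / n
  visit <- if (is.null(nSampleIterations)) seq_len(n) else
    .withSeed(seed, sample.int(n, min(nSampleIterations, n)))
  w <- numeric(m)
  for (a in visit) {
    own <- y[a]
    hits <- setdiff(which(y == own), a)
    contrib <- numeric(m)
    if (length(hits)) {
      kh <- min(kNeighbors, length(hits))
      nb <- hits[order(Dm[a, hits], hits)][seq_len(kh)]
      contrib <- contrib -
        rowMeans(abs(Xn[, nb, drop = FALSE] - Xn[, a]))
    }
    for (cls in setdiff(seq_len(classCount(train)), own)) {
      miss <- which(y == cls)
      km <- min(kNeighbors, length(miss))
      nb <- miss[order(Dm[a, miss], miss)][seq_len(km)]
      contrib <- contrib + (prior[cls] / (1 - prior[own])) *
        rowMeans(abs(Xn[, nb, drop = FALSE] - Xn[, a]))
    }
    w <- w + contrib
  }
  w <- w / length(visit)
  new("GeneWeights", weights = w,
      ranking = as.integer(order(-w, seq_along(w))),
      geneIds = geneIds(train))
}

#' Restrict a dataset to its top-weighted genes
#'
#' Returns the dataset restricted to the k highest-weight genes, in
#' descending-weight order (ties broken by ascending gene index); labels are
#' untouched.
#'
#' @param dataset an [ExpressionDataset-class]
#' @param weights a [GeneWeights-class] computed on the same gene set.
#' @param k number of genes to keep (<= number of genes).
#' @return an [ExpressionDataset-class] with k genes
#' @export
selectTopGenes <- function(dataset, weights, k) {
  stopifnot(is(dataset, "ExpressionDataset"), is(weights, "GeneWeights"))
  if (length(weights@weights) != nGenes(dataset))
    stop("weights were computed on a different gene set")
  if (k > nGenes(dataset))
    stop("k (", k, ") exceeds the number of genes (", nGenes(dataset), ")")
  dataset[weights@ranking[seq_len(k)], ]
}
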