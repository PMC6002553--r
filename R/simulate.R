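#' Simulate class-structured expression data with optional spike corruption
#'
#' Emulates the statistical structure the classifier assumes: each class has
#' its own block of informative genes whose class mean is shifted by
#' \code{meanShift} within-class standard deviations, all entries carry
#' i.i.d. Gaussian noise, and each entry is independently corrupted with
#' probability \code{corruptionRate} by an additive spike of magnitude
#' \code{corruptionScale} noise SDs with random sign — the heavy-tailed
#' outlier contamination the robust coder exists to absorb. Informative
#' genes are the first \code{informativeGenes} gene indices, dealt
#' round-robin to the classes.
#'
#' The default makes every gene informative for exactly one class: the
#' generator emulates expression profiles after discriminative gene
#' selection (as in the standard ReliefF top-k preprocessing), where
#' essentially every retained gene separates at least one class. Lower the
#' fraction to emulate an unscreened panel.
#'
#' @param nClasses number of classes.
#' @param nGenes total genes m.
#' @param samplesPerClass samples per class, a scalar or a vector of length
#'   \code{nClasses}.
#' @param informativeGenes genes carrying a class-mean shift (default: all
#'   genes).
#' @param meanShift class-mean shift in units of the noise SD.
#' @param noiseSd Gaussian noise standard deviation.
#' @param corruptionRate per-entry spike probability in [0, 1).
#' @param corruptionScale spike magnitude in noise-SD units.
#' @param seed RNG seed; the result is deterministic per seed.
#' @return list with \code{dataset} (an [ExpressionDataset-class]),
#'   \code{informative} (gene indices), \code{geneClass} (class whose mean
#'   is shifted on each informative gene) and \code{corrupted} (logical
#'   mask of spiked entries)
#' @export
simulateClassMeanData <- function(nClasses = 3L, nGenes = 50L,
                                  samplesPerClass = 15L,
                                  informativeGenes = nGenes,
                                  meanShift = 3, noiseSd = 1,
                                  corruptionRate = 0, corruptionScale = 10,
                                  seed = NULL) {
  if (informativeGenes > nGenes)
    stop("informativeGenes exceeds the gene count")
  if (corruptionRate < 0 || corruptionRate >= 1)
    stop("corruptionRate must lie in [0, 1)")
  if (nClasses < 1L || nGenes < 1L || any(samplesPerClass < 1L))
    stop("counts must be positive")
  nPer <- rep_len(samplesPerClass, nClasses)
  n <- sum(nPer)
  labels <- rep(seq_len(nClasses), nPer)
  informative <- seq_len(informativeGenes)
  geneClass <- if (informativeGenes)
    ((informative - 1L) %% nClasses) + 1L else integer(0)
  .withSeed(seed, {
    M <- matrix(0, nGenes, n)
    for (g in informative)
      M[g, labels == geneClass[g]] <- meanShift * noiseSd
    X <- M + matrix(stats::rnorm(nGenes * n, sd = noiseSd), nGenes, n)
    corrupted <- matrix(stats::runif(nGenes * n) < corruptionRate,
                        nGenes, n)
    if (any(corrupted)) {
      sgn <- sample(c(-1, 1), sum(corrupted), replace = TRUE)
      X[corrupted] <- X[corrupted] + sgn * corruptionScale * noiseSd
    }
    list(dataset = ExpressionDataset(X, labels),
         informative = informative, geneClass = geneClass,
         corrupted = corrupted)
  })
}

#' Simulate data from planted class-specific dictionaries
#'
#' Each class gets a random orthonormal sub-dictionary; each sample is a
#' k-sparse nonnegative-magnitude combination of its class atoms plus
#' Gaussian noise. Ground truth (dictionary and codes) is returned for
#' recovery tests.
#'
#' @param nGenes genes m.
#' @param atomsPerClass atoms per class sub-dictionary.
#' @param nClasses number of classes.
#' @param samplesPerClass samples per class.
#' @param sparsityK nonzero atoms per sample (<= atomsPerClass).
#' @param noiseSd Gaussian noise SD.
#' @param seed RNG seed.
#' @return list with \code{dataset}, \code{dictionary} (the true
#'   [StructuredDictionary-class]) and \code{coefficients} (true p x n
#'   codes)
#' @export
simulateDictionaryData <- function(nGenes = 30L, atomsPerClass = 3L,
                                   nClasses = 3L, samplesPerClass = 15L,
                                   sparsityK = 2L, noiseSd = 0.01,
                                   seed = NULL) {
  if (sparsityK > atomsPerClass)
    stop("sparsityK must not exceed atomsPerClass")
  if (atomsPerClass > nGenes)
    stop("atomsPerClass must not exceed the gene count")
  .withSeed(seed, {
    p <- atomsPerClass * nClasses
    n <- samplesPerClass * nClasses
    atoms <- matrix(0, nGenes, p)
    for (i in seq_len(nClasses)) {
      G <- matrix(stats::rnorm(nGenes * atomsPerClass), nGenes)
      atoms[, (i - 1L) * atomsPerClass + seq_len(atomsPerClass)] <-
        qr.Q(qr(G))[, seq_len(atomsPerClass), drop = FALSE]
    }
    dict <- new("StructuredDictionary", atoms = atoms,
                atomClass = rep(seq_len(nClasses), each = atomsPerClass))
    coefs <- matrix(0, p, n)
    labels <- rep(seq_len(nClasses), each = samplesPerClass)
    for (j in seq_len(n)) {
      own <- (labels[j] - 1L) * atomsPerClass + seq_len(atomsPerClass)
      supp <- own[sample.int(atomsPerClass, sparsityK)]
      coefs[supp, j] <- stats::runif(sparsityK, 1, 2) *
        sample(c(-1, 1), sparsityK, replace = TRUE)
    }
    X <- atoms %*% coefs +
      matrix(stats::rnorm(nGenes * n, sd = noiseSd), nGenes, n)
    list(dataset = ExpressionDataset(X, labels), dictionary = dict,
         coefficients = coefs)
  })
}
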