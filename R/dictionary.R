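#' Initialise a structured dictionary from class-wise singular vectors
#'
#' Each class sub-dictionary starts as the leading left singular vectors of
#' that class's sample block (the eigenvector basis of its scatter), giving
#' mutually orthonormal unit-norm atoms per class. Signs are fixed so the
#' largest-magnitude entry of every atom is positive, which makes the
#' initialisation deterministic.
#'
#' The \code{"auto"} atom budget is
#' \code{max(1, min(n_i, m, floor(m / (2c))))} per class: enough leading
#' eigenvectors to capture the class structure while keeping the stacked
#' dictionary at most half-complete. When class sub-dictionaries approach
#' the ambient gene dimension, every class can reconstruct every sample and
#' both the class-restricted residual and the coefficient centers lose
#' their discriminative value; capping the budget preserves class
#' specificity. Pass explicit counts to override (e.g. the full
#' \code{min(n_i, m)} eigenbasis).
#'
#' @param train an [ExpressionDataset-class]
#' @param atomsPerClass number of atoms per class, a single integer (or one
#'   per class), or "auto" (see above).
#' @return a [StructuredDictionary-class]
#' @export
initDictionary <- function(train, atomsPerClass = "auto") {
  stopifnot(is(train, "ExpressionDataset"))
  X <- exprValues(train)
  y <- sampleLabels(train)
  cc <- classCount(train)
  m <- nrow(X)
  auto <- identical(atomsPerClass, "auto")
  if (!auto) atomsPerClass <- rep_len(as.integer(atomsPerClass), cc)
  atoms <- vector("list", cc)
  for (i in seq_len(cc)) {
    Xi <- X[, y == i, drop = FALSE]
    pmax_i <- min(ncol(Xi), m)
    pi <- if (auto) max(1L, min(pmax_i, m %/% (2L * cc))) else
      atomsPerClass[i]
    if (pi > pmax_i)
      stop(sprintf("class %d: %d atoms requested but only %d basis vectors attainable",
                   i, pi, pmax_i))
    U <- svd(Xi, nu = pi, nv = 0)$u
    # deterministic sign convention
    for (j in seq_len(ncol(U)))
      if (U[which.max(abs(U[, j])), j] < 0) U[, j] <- -U[, j]
    U <- sweep(U, 2L, sqrt(colSums(U^2)), "/")
    atoms[[i]] <- U
  }
  new("StructuredDictionary",
      atoms = do.call(cbind, atoms),
      atomClass = rep(seq_len(cc), vapply(atoms, ncol, 1L)))
}

#' Atom-wise dictionary update for one class
#'
#' With all coefficients fixed, the class-i sub-dictionary minimises a
#' quadratic fit to the stacked target \eqn{\Lambda_i = [\tilde X, X_i, 0]}
#' against the stacked coefficient rows \eqn{Z_i}, one atom at a time in
#' index order with the closed form \eqn{d_j = Y z_j^T / \|Y z_j^T\|_2},
#' where \eqn{Y = \Lambda_i - \sum_{l \ne j} d_l z_l}. Every updated atom is
#' unit-norm by construction and the quadratic objective never increases
#' over the sweep. An atom whose update direction vanishes (dead atom) is
#' left unchanged with a warning.
#'
#' @param classId class to update.
#' @param dict current [StructuredDictionary-class].
#' @param coef p x n training coefficient matrix.
#' @param train the training [ExpressionDataset-class].
#' @return list with elements \code{dictionary} (updated), and
#'   \code{objectiveBefore} / \code{objectiveAfter}, the stacked quadratic
#'   objective around the sweep.
#' @export
updateDictionaryClass <- function(classId, dict, coef, train) {
  X <- exprValues(train)
  y <- sampleLabels(train)
  cc <- classCount(dict)
  if (classId < 1L || classId > cc) stop("class index out of range")
  rows_i <- .atomIdx(dict, classId)
  m <- nrow(X); n <- ncol(X)
  # residual of X after removing the other classes' contributions
  Xt <- X
  for (j in setdiff(seq_len(cc), classId)) {
    rj <- .atomIdx(dict, j)
    Xt <- Xt - dict@atoms[, rj, drop = FALSE] %*% coef[rj, , drop = FALSE]
  }
  idx_i <- which(y == classId)
  othersCols <- lapply(setdiff(seq_len(cc), classId), function(j)
    coef[rows_i, y == j, drop = FALSE])
  Lambda <- cbind(Xt, X[, idx_i, drop = FALSE],
                  matrix(0, m, n - length(idx_i)))
  Z <- cbind(coef[rows_i, , drop = FALSE],
             coef[rows_i, idx_i, drop = FALSE],
             do.call(cbind, c(othersCols, list(matrix(0, length(rows_i), 0)))))
  Di <- dict@atoms[, rows_i, drop = FALSE]
  R <- Lambda - Di %*% Z
  before <- sum(R^2)
  for (j in seq_along(rows_i)) {
    zj <- Z[j, ]
    v <- drop(R %*% zj) + Di[, j] * sum(zj^2)   # Y z_j^T
    nrm <- .l2(v)
    if (nrm < 1e-12) {
      warning("dead atom ", rows_i[j], " (class ", classId,
              "): update direction vanished, atom left unchanged",
              call. = FALSE)
      next
    }
    dnew <- v / nrm
    R <- R + outer(Di[, j] - dnew, zj)
    Di[, j] <- dnew
  }
  after <- sum(R^2)
  atoms <- dict@atoms
  atoms[, rows_i] <- Di
  list(dictionary = new("StructuredDictionary", atoms = atoms,
                        atomClass = dict@atomClass),
       objectiveBefore = before, objectiveAfter = after)
}
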