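# Independent oracles and small fixture builders. These deliberately use
# naive scalar loops / exhaustive enumeration so they share no code path
# with the package implementation they check.

# Exhaustive sign-pattern LASSO oracle for min 1/2||y - X a||^2 + lambda|a|_1:
# enumerate all sign patterns in {-1,0,1}^p, solve each KKT system, keep
# feasible stationary points, return the objective minimiser.
bruteLasso <- function(X, y, lambda) {
  p <- ncol(X)
  obj <- function(a) 0.5 * sum((y - X %*% a)^2) + lambda * sum(abs(a))
  best <- NULL
  bestVal <- Inf
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (r in seq_len(nrow(patterns))) {
    s <- patterns[r, ]
    A <- which(s != 0)
    a <- numeric(p)
    if (length(A)) {
      XA <- X[, A, drop = FALSE]
      G <- crossprod(XA)
      rhs <- crossprod(XA, y) - lambda * s[A]
      sol <- tryCatch(solve(G, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      if (any(sign(sol) * s[A] < 0)) next   # sign consistency (0 allowed)
      a[A] <- sol
    }
    g <- crossprod(X, y - X %*% a)
    if (length(A) < p && any(abs(g[-A]) > lambda + 1e-9) && length(A) > 0) next
    if (length(A) == 0 && any(abs(g) > lambda + 1e-9)) next
    v <- obj(a)
    if (v < bestVal) { bestVal <- v; best <- a }
  }
  best
}

# Naive multi-class ReliefF with plain loops over genes and neighbours,
# all instances visited, range-normalised differences.
bruteReliefF <- function(X, y, k) {
  m <- nrow(X); n <- ncol(X)
  rng <- apply(X, 1, function(r) max(r) - min(r))
  diffg <- function(g, a, b) {
    if (rng[g] == 0) return(0)
    abs(X[g, a] - X[g, b]) / rng[g]
  }
  distab <- function(a, b) sum(vapply(seq_len(m), diffg, 0, a = a, b = b))
  prior <- table(factor(y, levels = sort(unique(y)))) / n
  w <- numeric(m)
  for (a in seq_len(n)) {
    for (g in seq_len(m)) {
      hits <- setdiff(which(y == y[a]), a)
      dh <- vapply(hits, distab, 0, a = a)
      kh <- min(k, length(hits))
      nh <- hits[order(dh, hits)][seq_len(kh)]
      hit <- mean(vapply(nh, diffg, 0, g = g, a = a))
      miss <- 0
      for (cl in setdiff(sort(unique(y)), y[a])) {
        mi <- which(y == cl)
        dm <- vapply(mi, distab, 0, a = a)
        km <- min(k, length(mi))
        nm <- mi[order(dm, mi)][seq_len(km)]
        miss <- miss + (prior[[cl]] / (1 - prior[[y[a]]])) *
          mean(vapply(nm, diffg, 0, g = g, a = a))
      }
      w[g] <- w[g] + (miss - hit) / n
    }
  }
  w
}

# scalar-loop evaluation of the class fidelity term
bruteFidelity <- function(Xi, D, atomClass, alphaI, classId) {
  recAll <- D %*% alphaI
  v <- sum((Xi - recAll)^2)
  for (j in sort(unique(atomClass))) {
    rj <- which(atomClass == j)
    rec <- D[, rj, drop = FALSE] %*% alphaI[rj, , drop = FALSE]
    v <- v + if (j == classId) sum((Xi - rec)^2) else sum(rec^2)
  }
  v
}

# scatter traces via explicit outer-product matrices
bruteScatter <- function(coef, labels) {
  p <- nrow(coef)
  m <- rowMeans(coef)
  SW <- matrix(0, p, p); SB <- matrix(0, p, p)
  for (i in sort(unique(labels))) {
    idx <- which(labels == i)
    mi <- rowMeans(coef[, idx, drop = FALSE])
    for (k in idx) SW <- SW + tcrossprod(coef[, k] - mi)
    SB <- SB + length(idx) * tcrossprod(mi - m)
  }
  list(tr_sw = sum(diag(SW)), tr_sb = sum(diag(SB)))
}

# largest principal angle (degrees) between the column spans of A and B
principalAngleDeg <- function(A, B) {
  QA <- qr.Q(qr(A)); QB <- qr.Q(qr(B))
  sv <- svd(crossprod(QA, QB))$d
  acos(min(1, max(-1, min(sv)))) * 180 / pi
}

# small labelled dataset with distinct class means
makeTinyDataset <- function(nClasses = 2, nGenes = 6, perClass = 4,
                            shift = 2, seed = 1) {
  set.seed(seed)
  labels <- rep(seq_len(nClasses), each = perClass)
  X <- matrix(rnorm(nGenes * length(labels)), nGenes)
  for (i in seq_len(nClasses))
    X[i, labels == i] <- X[i, labels == i] + shift
  ExpressionDataset(X, labels)
}
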