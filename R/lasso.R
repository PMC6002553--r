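#' Component-wise soft thresholding
#'
#' The proximal operator of the L1 norm: each component is shrunk toward
#' zero by t and zeroed when its magnitude is at most t. Equivalently the
#' minimiser of \eqn{\frac{1}{2}\sigma (x - v)^2 + \tau |x|} with
#' \eqn{t = \tau/\sigma}.
#'
#' @param v numeric vector.
#' @param t nonnegative threshold.
#' @return vector of the same length as v
#' @examples
#' softThreshold(c(2, -0.3, 0), 0.5)
#' @export
softThreshold <- function(v, t) {
  if (t < 0) stop("threshold must be nonnegative")
  sign(v) * pmax(abs(v) - t, 0)
}

# Cyclic coordinate descent for min_a 1/2 ||y - X a||_2^2 + lambda ||a||_1
# on the raw (unscaled, no-intercept) objective. Zero-norm columns keep a
# zero coefficient. Terminates on the KKT residual, so solutions satisfy the
# subgradient optimality conditions to `kktTol`.
.lassoCD <- function(X, y, lambda, kktTol = 1e-8, maxSweeps = 20000L,
                     init = NULL) {
  if (lambda < 0) stop("the L1 weight must be nonnegative")
  p <- ncol(X)
  xtx <- colSums(X^2)
  if (is.null(init)) {
    a <- numeric(p)
    r <- y
  } else {
    a <- init
    a[xtx == 0] <- 0
    r <- y - drop(X %*% a)
  }
  active <- which(xtx > 0)
  for (sweep in seq_len(maxSweeps)) {
    delta <- 0
    for (j in active) {
      z <- sum(X[, j] * r) + xtx[j] * a[j]
      az <- abs(z) - lambda                    # scalar soft threshold
      anew <- if (az <= 0) 0 else sign(z) * az / xtx[j]
      if (anew != a[j]) {
        r <- r - X[, j] * (anew - a[j])
        delta <- max(delta, abs(anew - a[j]))
        a[j] <- anew
      }
    }
    if (delta <= 1e-12 * (1 + max(abs(a)))) {
      g <- drop(crossprod(X, r))               # X^T (y - X a)
      kkt <- max(0, abs(g[active]) - lambda,
                 abs(g[active][a[active] != 0] -
                     lambda * sign(a[active][a[active] != 0])))
      if (kkt <= kktTol || delta == 0) break   # delta 0: a fixed point
    }
  }
  a
}
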