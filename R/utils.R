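# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. NULL seed = use the current stream.
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

.l2 <- function(x) sqrt(sum(x^2))

# indices of atoms belonging to class i
.atomIdx <- function(dict, i) which(dict@atomClass == i)

# stable log(1 + exp(z))
.log1pexp <- function(z) {
  out <- numeric(length(z))
  hi <- z > 33
  lo <- !hi
  out[hi] <- z[hi]
  out[lo] <- log1p(exp(z[lo]))
  out
}

# stable logistic, clamped to the open interval (0, 1)
.logistic <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  eps <- .Machine$double.xmin
  pmin(pmax(out, eps), 1 - .Machine$double.eps / 2)
}
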