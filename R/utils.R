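# Internal helpers shared across modules.

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the current stream untouched.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a stream of sub-seeds below 2^31 from a master seed.
.subSeeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Dirichlet draws, one row per observation.
.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  sweep(x, 1, rowSums(x), "/")
}

# Multivariate hypergeometric draw: subsample `depth` items without
# replacement from categories with counts `x` (integer vector).
.rmvhyper <- function(x, depth) {
  nm <- names(x)
  x <- as.integer(round(x))
  out <- integer(length(x))
  names(out) <- nm
  left <- sum(x)
  k <- as.integer(depth)
  for (i in seq_along(x)) {
    if (k == 0L) break
    left <- left - x[i]
    out[i] <- stats::rhyper(1L, x[i], left, k)
    k <- k - out[i]
  }
  out
}

# Benjamini-Hochberg shorthand.
.bh <- function(p) stats::p.adjust(p, method = "BH")

# Dense ranks of descending abundance within a sample (rank 1 = most
# abundant); ties share a rank and do not create gaps.
.denseRankDesc <- function(v) {
  u <- sort(unique(-v))
  match(-v, u)
}

# Adjusted Rand index (used by recovery tests; falls back to an internal
# computation when mclust is unavailable at run time).
.ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- ai * bj / n2
  (nij - exp_) / ((ai + bj) / 2 - exp_)
}
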