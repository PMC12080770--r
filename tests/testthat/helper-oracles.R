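# Independent oracles and small fixture builders used across the suite.

# alternating two-value RR series: 990, 1010, 990, ...
alternatingSeries <- function(n = 240, lo = 990, hi = 1010) {
  rep(c(lo, hi), length.out = n)
}

# line-by-line transcription of the entropy weight formulas, deliberately
# naive (explicit loops) and independent of the package implementation;
# takes an already shifted matrix (all entries > 0)
entropyOracle <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  p <- matrix(0, n, k)
  for (j in seq_len(k)) {
    s <- 0
    for (i in seq_len(n)) s <- s + m[i, j]
    for (i in seq_len(n)) p[i, j] <- m[i, j] / s
  }
  e <- numeric(k)
  for (j in seq_len(k)) {
    acc <- 0
    for (i in seq_len(n)) acc <- acc + p[i, j] * log(p[i, j])
    e[j] <- -acc / log(n)
  }
  g <- 1 - e
  list(p = p, e = e, g = g, w = g / sum(g))
}

# exhaustive best 2-partition by within-cluster sum of squares to the
# partition means (brute force over all non-trivial label assignments)
bruteForceBestSS2 <- function(points) {
  n <- nrow(points)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {  # fix point 1 in cluster 1; skip all-one
    lab <- c(1L, as.integer(intToBits(code))[1:(n - 1)] + 1L)
    ss <- 0
    for (cl in 1:2) {
      sub <- points[lab == cl, , drop = FALSE]
      ctr <- colMeans(sub)
      ss <- ss + sum(sweep(sub, 2, ctr)^2)
    }
    if (ss < best) best <- ss
  }
  best
}

# two well-separated Gaussian blobs in 2-D
makeBlobs <- function(centers, nPer = 10, sd = 0.1, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(nPer, centers[i, 1], sd), rnorm(nPer, centers[i, 2], sd))))
}

# small deterministic cohort used by several files (cached per session)
defaultCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulateCohort(protocolConfig(seed = 101))
    cache
  }
})
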