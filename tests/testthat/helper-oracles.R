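# Independent brute-force oracles used by the statistical tests.

# AMI via naive loops; the hypergeometric expectation term uses dhyper
# directly instead of the log-gamma expansion in the implementation.
ami_oracle <- function(truth, pred) {
  ti <- as.integer(factor(truth))
  pi <- as.integer(factor(pred))
  n <- length(ti)
  cont <- unclass(table(ti, pi))
  a <- rowSums(cont)
  b <- colSums(cont)
  if (length(a) == 1 && length(b) == 1) return(1)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- cont[i, j]
    if (nij > 0) mi <- mi + nij / n * log(n * nij / (a[i] * b[j]))
  }
  hu <- -sum((a / n) * log(a / n))
  hv <- -sum((b / n) * log(b / n))
  emi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    lo <- max(1, a[i] + b[j] - n)
    hi <- min(a[i], b[j])
    if (hi < lo) next
    for (nij in lo:hi) {
      emi <- emi + stats::dhyper(nij, b[j], n - b[j], a[i]) *
        nij / n * log(n * nij / (a[i] * b[j]))
    }
  }
  denom <- (hu + hv) / 2 - emi
  eps <- .Machine$double.eps
  denom <- if (denom < 0) min(denom, -eps) else max(denom, eps)
  unname((mi - emi) / denom)
}

# Hypergeometric overlap tail probability by exhaustive enumeration of every
# possible draw of size_b elements from the universe.
overlap_oracle <- function(size_a, size_b, n_overlap, universe_size) {
  draws <- utils::combn(universe_size, size_b)
  in_a <- seq_len(size_a)
  mean(apply(draws, 2, function(cols) sum(cols %in% in_a) >= n_overlap))
}
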