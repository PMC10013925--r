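# Independent oracles, deliberately implemented along different routes
# than the package code they check.

# Smallest c with sum_{k<=c} dbinom(k; m, 1/B) >= 1 - alpha/B, by direct
# summation of the pmf. The 1e-9 slack only absorbs accumulation error at
# exact CDF ties (e.g. m = 2, B = 20, alpha = 0.05 hits the target
# probability exactly); binomial pmf steps near the quantile are orders
# of magnitude larger.
qc_threshold_bruteforce <- function(m, bins, alpha) {
  target <- 1 - alpha / bins
  cdf <- cumsum(stats::dbinom(0:m, m, 1 / bins))
  which(cdf >= target - 1e-9)[1L] - 1L
}

# Rank-based q-value-averaging pi0, written as an explicit loop over the
# ascending order statistics: the k-th smallest p-value has top-rank
# weight k and capped q-value min(n p_(k) / k, 1).
pi0_lfdr_loop <- function(p) {
  n <- length(p)
  ps <- sort(p)
  acc <- 0
  for (k in seq_len(n)) {
    acc <- acc + k * min(n * ps[k] / k, 1)
  }
  min(max(2 * acc / (n * (n + 1)), 0), 1)
}

# a table mimicking DESeq2 output with independent expression values
synthetic_expression_table <- function(p, log2_range = c(0, 8)) {
  n <- length(p)
  data.frame(
    baseMean = 2^stats::runif(n, log2_range[1], log2_range[2]),
    pvalue = p
  )
}
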