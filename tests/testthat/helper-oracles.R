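# Independent brute-force oracles used to check the implementation.

# Literal Benjamini-Hochberg step-up: sort, q_(i) = min_{j >= i} p_(j)*m/j,
# cap at 1, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Exact hypergeometric upper-tail by enumeration of the pmf.
hyper_tail_oracle <- function(k, n_list, K_unit, N) {
  if (k <= 0) return(1)
  hi <- min(n_list, K_unit)
  sum(stats::dhyper(k:hi, K_unit, N - K_unit, n_list))
}
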