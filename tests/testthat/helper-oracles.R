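# Independent enumeration oracles for the exact tests.

# exact McNemar: enumerate the Binomial(b + c, 1/2) null directly
mcnemar_enum_oracle <- function(b, c_) {
  n <- b + c_
  probs <- choose(n, 0:n) * 0.5^n
  m <- min(b, c_)
  extreme <- (0:n) <= m | (0:n) >= n - m
  min(1, sum(probs[extreme]))
}

# two-sided Fisher: explicit binomial-coefficient enumeration of all
# tables sharing the observed margins
fisher_enum_oracle <- function(a, b, c_, d) {
  m <- a + b; n2 <- c_ + d; k <- a + c_
  xs <- max(0, k - n2):min(k, m)
  probs <- choose(m, xs) * choose(n2, k - xs) / choose(m + n2, k)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
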