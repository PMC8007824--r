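# Independent brute-force oracles for the exact tests, built directly on
# binomial coefficients (never on dhyper/phyper, which the implementations
# use).

# P[X = k] for X ~ Hypergeometric(N, m, n): overlap of a fixed m-set with a
# random n-draw from an N-universe
oracle_hyper_pmf <- function(k, N, m, n) {
  exp(lchoose(m, k) + lchoose(N - m, n - k) - lchoose(N, n))
}

# upper tail P[X >= q]
oracle_hyper_tail <- function(q, N, m, n) {
  lo <- max(0, m + n - N)
  hi <- min(m, n)
  if (q > hi) return(0)
  sum(oracle_hyper_pmf(max(q, lo):hi, N, m, n))
}

# two-sided Fisher p for table rbind(c(a, b), c(c, d)): enumerate every
# table with the observed margins, sum the probabilities of those no more
# probable than the observed one
oracle_fisher_two_sided <- function(a, b, c_, d) {
  m <- a + c_; n <- b + d; k <- a + b; N <- m + n
  support <- max(0, k - n):min(k, m)
  dens <- vapply(support, oracle_hyper_pmf, numeric(1), N = N, m = m, n = k)
  p_obs <- dens[match(a, support)]
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}

# one-sided binomial upper tail P[X >= x], X ~ Binomial(n, p), from the
# closed-form pmf
oracle_binom_tail <- function(x, n, p) {
  if (x > n) return(0)
  k <- x:n
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}
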