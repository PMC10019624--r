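# independent brute-force oracles for the detection statistics

bruteforce_binom_tail <- function(n, k, p) {
  if (k == 0) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

bruteforce_bh <- function(p, m) {
  # O(m^2) step-up: q_i = min over ranks >= rank(i) of p_(j) * m / j
  o <- order(p)
  r <- order(o)  # rank of each p
  n <- length(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    vals <- vapply(r[i]:n, function(j) p[o[j]] * m / j, numeric(1))
    q[i] <- min(1, vals)
  }
  q
}
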