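# Independent oracles used to cross-check the package's statistics.
# These deliberately re-derive each quantity from first principles and
# share no code with the implementation.

# Two-sided Fisher exact p by exhaustive enumeration over all tables
# with the observed margins, summing hypergeometric point masses not
# exceeding the observed table's (with a relative tolerance for ties).
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  pt <- function(a) dhyper(a, r1, r2, c1)
  p_obs <- pt(tab[1, 1])
  sum(vapply(lo:hi, pt, numeric(1))[vapply(lo:hi, pt, numeric(1)) <=
                                      p_obs * (1 + 1e-7)])
}

# Direct transliteration of the adjusted-entropy formulas, computed
# step by step on one numeric vector.
oracle_hq <- function(m, eps = 1e-4) {
  n <- length(m)
  med <- sort(m)[c(floor((n + 1) / 2), ceiling((n + 1) / 2))]
  med <- mean(med)
  devs <- sort(abs(m - med))[c(floor((n + 1) / 2), ceiling((n + 1) / 2))]
  mad_r <- mean(devs)
  u <- (m - med) / (5 * mad_r + 1e-4)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  tbr <- sum(w * m) / sum(w)
  d <- abs(m - tbr)
  if (sum(d) == 0) return(Inf)
  p <- d / sum(d)
  hp <- -sum(vapply(p, function(x) if (x > 0) x * log2(x) else 0,
                    numeric(1)))
  hp * abs(log2(max(m) - min(m) + eps))
}

# Upper-tail hypergeometric probability by explicit summation.
oracle_hyper_tail <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
}
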