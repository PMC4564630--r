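# Independent statistical oracles, coded separately from the package paths
# they check.

# Exact Mann-Whitney two-sided p by brute-force enumeration over all
# labelings, built from the null distribution of the rank sum W (not U).
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  r <- rank(c(x, y), ties.method = "average")
  W_obs <- sum(r[seq_len(n1)])
  W_all <- apply(utils::combn(N, n1), 2, function(idx) sum(r[idx]))
  p_le <- mean(W_all <= W_obs + 1e-9)
  p_ge <- mean(W_all >= W_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Kruskal-Wallis H evaluated directly from the rank-sum formula with the
# tie-correction denominator.
oracle_kw_H <- function(groups) {
  v <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(v)
  r <- rank(v, ties.method = "average")
  Rj <- tapply(r, g, sum)
  nj <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  tab <- table(v)
  H / (1 - sum(tab^3 - tab) / (N^3 - N))
}
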