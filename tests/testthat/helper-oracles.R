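# brute-force oracles, independent of the package implementations

# Friedman statistic recomputed from scratch on a rank matrix
friedman_stat_oracle <- function(X) {
  R <- t(apply(X, 1, rank))
  n <- nrow(R); k <- ncol(R)
  A <- sum(R^2); C <- n * k * (k + 1)^2 / 4
  if (A - C <= 1e-12) return(0)
  (k - 1) * sum((colSums(R) - n * (k + 1) / 2)^2) / (A - C)
}

# exact permutation p by full enumeration of per-row orderings
friedman_p_oracle <- function(X) {
  n <- nrow(X); k <- ncol(X)
  R <- t(apply(X, 1, rank))
  perms <- pracma::perms(seq_len(k))
  grids <- do.call(expand.grid, rep(list(seq_len(nrow(perms))), n))
  S <- function(Rm) sum((colSums(Rm) - n * (k + 1) / 2)^2)
  s_obs <- S(R)
  hits <- apply(grids, 1, function(g) {
    Rp <- t(vapply(seq_len(n), function(i) R[i, perms[g[i], ]],
                   numeric(k)))
    S(Rp) >= s_obs - 1e-9
  })
  mean(hits)
}

# signed-rank: exact two-sided p by enumerating all 2^m sign assignments
signed_rank_oracle <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  W <- signs %*% r
  mu <- m * (m + 1) / 4
  p <- min(1, 2 * min(mean(W <= w_obs + 1e-9), mean(W >= w_obs - 1e-9)))
  list(W = w_obs, p = p)
}
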