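# Shared helpers: independent oracles and convenience parameter sets.

default_pcm <- function(...) pcm_params(...)

# Stationary distribution of the bound-count chain by solving the full
# (N+1)-state generator matrix (null space of t(Q) with a normalization
# row) — independent of the detailed-balance recursion in the package.
stationary_nullspace <- function(f, params) {
  rates <- pcm_effective_rates(f, params)
  g <- rates$forward
  r <- rates$reverse
  n <- params$N + 1L
  Q <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    Q[i, i + 1] <- g[i]       # i-1 -> i binding
    Q[i + 1, i] <- r[i]       # i -> i-1 unbinding
  }
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q)[-1, , drop = FALSE], rep(1, n))
  as.numeric(solve(A, c(rep(0, n - 1), 1)))
}

# total-variation distance between two distributions on the same support
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))
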