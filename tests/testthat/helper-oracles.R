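# Independent oracles: brute-force enumerations and direct formulas kept
# deliberately separate from the package's implementations.

# Signed-rank p by exhaustive enumeration over all 2^n sign assignments.
enum_signed_rank_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  if (length(d) == 0L) return(1)
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  # every sign vector
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- signs %*% r
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p_le <- mean(w_all <= w_obs + 1e-9)
  switch(alternative,
    greater = p_ge,
    less = p_le,
    two.sided = min(1, 2 * min(p_ge, p_le))
  )
}

# Rank-sum p by exhaustive enumeration over all C(n1+n2, n1) group labelings.
enum_rank_sum_p <- function(x, y, alternative = "two.sided") {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  subsets <- utils::combn(length(r), n1)
  w_all <- apply(subsets, 2, function(idx) sum(r[idx]))
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p_le <- mean(w_all <= w_obs + 1e-9)
  switch(alternative,
    greater = p_ge,
    less = p_le,
    two.sided = min(1, 2 * min(p_ge, p_le))
  )
}

# BH by the stepwise formula: q_(i) = min_{j >= i} m p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Chi-square upper tail by numerical integration of the density.
chisq_tail_integrate <- function(x, df) {
  stats::integrate(function(t) stats::dchisq(t, df), lower = x, upper = Inf,
                   rel.tol = 1e-12)$value
}

# Seeded random difference vectors with ties and zeros for oracle sweeps.
draw_diffs <- function(n, seed) {
  set.seed(seed)
  d <- sample(c(-3L:3L), n, replace = TRUE) + sample(c(0, 0, 0.5), n, replace = TRUE)
  d
}
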