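# Generators for random and exactly in-sample-calibrated samples used
# across the measure, curve and comparison tests.

random_sample <- function(n = 50, ties = FALSE) {
  p <- stats::runif(n)
  if (ties) p <- round(p, 1)  # force tied predicted values
  d <- stats::rbinom(n, 1, 0.5)
  if (sum(d) == 0) d[sample(n, 1)] <- 1
  if (sum(d) == n) d[sample(n, 1)] <- 0
  list(d = d, p = p)
}

# Exactly calibrated: subjects come in groups sharing a predicted value
# v = k/m, with k diseased out of m in each group, so the mean outcome
# at every distinct predicted value equals that value.
calibrated_sample <- function(n_groups = 5) {
  d <- integer(0)
  p <- numeric(0)
  for (g in seq_len(n_groups)) {
    m <- sample(2:6, 1)
    k <- sample(seq_len(m - 1), 1)
    d <- c(d, rep(1, k), rep(0, m - k))
    p <- c(p, rep(k / m, m))
  }
  idx <- sample(length(d))
  list(d = d[idx], p = p[idx])
}

# A pair of models that are both exactly calibrated on the same sample:
# the "new" model is a calibrated grouping and the "old" model merges
# adjacent groups, predicting each merged block's pooled event rate.
calibrated_pair <- function(n_groups = 6) {
  groups <- lapply(seq_len(n_groups), function(g) {
    m <- sample(2:6, 1)
    k <- sample(seq_len(m - 1), 1)
    list(m = m, k = k)
  })
  blocks <- split(seq_len(n_groups),
                  sort(sample(rep(1:3, length.out = n_groups))))
  d <- integer(0); p_new <- numeric(0); p_old <- numeric(0)
  for (bl in blocks) {
    m_tot <- sum(vapply(groups[bl], `[[`, numeric(1), "m"))
    k_tot <- sum(vapply(groups[bl], `[[`, numeric(1), "k"))
    for (g in bl) {
      m <- groups[[g]]$m; k <- groups[[g]]$k
      d <- c(d, rep(1, k), rep(0, m - k))
      p_new <- c(p_new, rep(k / m, m))
      p_old <- c(p_old, rep(k_tot / m_tot, m))
    }
  }
  idx <- sample(length(d))
  list(d = d[idx], old = p_old[idx], new = p_new[idx])
}

# Brute-force pairwise AUC, the oracle the rank-based route must match.
pairwise_auc <- function(d, p) {
  pd <- p[d == 1]; pn <- p[d == 0]
  s <- 0
  for (x in pd) s <- s + sum(x > pn) + 0.5 * sum(x == pn)
  s / (length(pd) * length(pn))
}
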