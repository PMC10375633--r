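# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops and textbook formulas, kept slow and obvious.

# Spearman rho of two vectors: Pearson on average ranks, computed by explicit
# summation.
oracle_spearman <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

# Tie-free shortcut 1 - 6*sum(d^2)/(n(n^2-1)); only valid without ties.
oracle_spearman_d2 <- function(a, b) {
  n <- length(a)
  d <- rank(a) - rank(b)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# PBSI of every subject by nested loops.
oracle_pbsi <- function(profiles) {
  n <- nrow(profiles)
  out <- numeric(n)
  for (s in seq_len(n)) {
    acc <- 0
    for (t in seq_len(n)) {
      if (t != s) acc <- acc + oracle_spearman(profiles[s, ], profiles[t, ])
    }
    out[s] <- acc / (n - 1)
  }
  out
}

# Leave-one-region-out contributions rebuilt from scratch per deletion.
oracle_contributions <- function(profiles) {
  full <- oracle_pbsi(profiles)
  out <- matrix(NA_real_, nrow(profiles), ncol(profiles))
  for (i in seq_len(ncol(profiles))) {
    out[, i] <- abs(full - oracle_pbsi(profiles[, -i, drop = FALSE]))
  }
  out
}

# BH step-up by the classical description: find the largest k with
# p_(k) <= k*q/m, reject the k smallest; q-values by direct minimisation.
oracle_bh <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  rejected <- logical(m)
  if (k > 0) rejected[o[seq_len(k)]] <- TRUE
  qs <- numeric(m)
  for (i in seq_len(m)) {
    qs[o[i]] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  list(q = qs, rejected = rejected)
}

# Small random cohort for property tests.
random_profiles <- function(n, r, seed) {
  set.seed(seed)
  matrix(rnorm(n * r), n, r, dimnames = list(paste0("s", 1:n), paste0("r", 1:r)))
}
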