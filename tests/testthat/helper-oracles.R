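# Independent brute-force oracles. These deliberately re-derive each
# statistic from first principles (explicit loops over pairs, subsets or the
# hypergeometric support) and share no code with the package internals.

# Within-population pi by all-pairs Hamming counting: per site, loop over
# every pair of called sequences; sum of per-site mean pairwise differences,
# divided by region length.
oracle_pi <- function(geno, region_len) {
  total <- 0
  n_usable <- 0
  for (s in seq_len(nrow(geno))) {
    x <- geno[s, ]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2) next
    n_usable <- n_usable + 1
    diffs <- 0
    pairs <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        diffs <- diffs + as.integer(x[i] != x[j])
        pairs <- pairs + 1
      }
    }
    total <- total + diffs / pairs
  }
  list(pi = total / region_len, n_usable = n_usable)
}

# Cross-population Dxy by enumerating every cross-population pair.
oracle_dxy <- function(geno_a, geno_b, region_len) {
  total <- 0
  n_usable <- 0
  for (s in seq_len(nrow(geno_a))) {
    a <- geno_a[s, ]; a <- a[!is.na(a)]
    b <- geno_b[s, ]; b <- b[!is.na(b)]
    if (length(a) < 1 || length(b) < 1) next
    n_usable <- n_usable + 1
    diffs <- 0
    for (i in seq_along(a)) {
      for (j in seq_along(b)) {
        diffs <- diffs + as.integer(a[i] != b[j])
      }
    }
    total <- total + diffs / (length(a) * length(b))
  }
  list(dxy = total / region_len, n_usable = n_usable)
}

# Two-sided Fisher exact p by full enumeration of the hypergeometric
# support: sum the probabilities of all tables (at fixed margins) no more
# probable than the observed one (tiny relative tolerance absorbs floating-
# point ties).
oracle_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b
  c1 <- a + c_
  n <- a + b + c_ + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric probability by direct summation.
oracle_hyper_tail <- function(k_obs, K, N, n) {
  ks <- k_obs:min(K, n)
  sum(vapply(ks, function(k) {
    choose(K, k) * choose(N - K, n - k) / choose(N, n)
  }, numeric(1)))
}

# Exact tail probability of the resampling statistic by exhaustive subset
# enumeration.
oracle_resample_tail <- function(low, m, observed) {
  subs <- utils::combn(length(low), m)
  stats <- apply(subs, 2, function(idx) sum(low[idx]))
  mean(stats >= observed)
}

# Benjamini-Hochberg step-up, written directly from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}
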