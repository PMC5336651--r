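# Independent oracle implementations: deliberately naive (explicit loops,
# no shared code with R/) so they can arbitrate the package's fast paths.

# random symmetric weight matrix with zero diagonal, entries in (0, 1)
rand_weights <- function(n, seed, labels = sprintf("v%02d", seq_len(n))) {
  m <- withr::with_seed(seed, {
    x <- matrix(0, n, n)
    x[upper.tri(x)] <- stats::runif(n * (n - 1) / 2)
    x + t(x)
  })
  dimnames(m) <- list(labels, labels)
  ConnectivityMatrix(m)
}

# a pair of connectivity matrices from a small permuted RG instance
rand_conn_pair <- function(n, d, k, seed) {
  inst <- makeInstance(simulationSpec("rg_permuted", N = n, d = d, k = k,
                                      seed = seed))
  list(Wa = cosineConnectivity(inst$graph_a),
       Wb = cosineConnectivity(inst$graph_b),
       gold = inst$gold, universe = nodeLabels(inst$graph_a))
}

oracle_center <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) tot <- tot + m[i, j]
  mbar <- tot / (n * (n - 1))
  out <- m
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- if (i == j) 0 else m[i, j] - mbar
  out
}

# GHD by direct summation over ordered off-diagonal pairs
oracle_ghd <- function(A, B) {
  n <- nrow(A)
  a <- oracle_center(A); b <- oracle_center(B)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    tot <- tot + (a[i, j] - b[i, j])^2
  tot / (n * (n - 1))
}

# exact permutation-null mean of the centered statistic: (S2a' + S2b') / D
oracle_mu <- function(A, B) {
  n <- nrow(A)
  a <- oracle_center(A); b <- oracle_center(B)
  (sum(a^2) + sum(b^2)) / (n * (n - 1))
}

oracle_cghd <- function(A, B) oracle_ghd(A, B) - oracle_mu(A, B)

# Monte-Carlo permutation oracle for the null moments
oracle_mc_null <- function(A, B, n_perm, seed) {
  n <- nrow(A)
  vals <- withr::with_seed(seed, replicate(n_perm, {
    p <- sample.int(n)
    oracle_ghd_fast(A[p, p], B)
  }))
  list(mean = mean(vals), var = stats::var(vals),
       se_mean = stats::sd(vals) / sqrt(n_perm))
}

# vectorized GHD (still independent of package internals); needed to keep
# the 20k-permutation oracle affordable
oracle_ghd_fast <- function(A, B) {
  n <- nrow(A)
  off <- !diag(n)
  a <- A[off]; b <- B[off]
  a <- a - mean(a); b <- b - mean(b)
  sum((a - b)^2) / (n * (n - 1))
}

# per-node decomposition by explicit loops (shares sum to ghd and mu)
oracle_contributions <- function(A, B) {
  n <- nrow(A)
  D <- n * (n - 1)
  a <- oracle_center(A); b <- oracle_center(B)
  S1a <- sum(a); S1b <- sum(b)
  ghd_i <- mu_i <- numeric(n)
  for (i in seq_len(n)) {
    qa <- sum(a[i, ]^2); qb <- sum(b[i, ]^2)
    ghd_i[i] <- sum((a[i, ] - b[i, ])^2) / D
    mu_i[i] <- (qa + qb) / D - (sum(a[i, ]) * S1b + sum(b[i, ]) * S1a) / D^2
  }
  list(ghd_i = ghd_i, mu_i = mu_i, contribution = ghd_i - mu_i)
}

# Mann-Whitney AUC by exhaustive pairwise comparison, ties counted 1/2
oracle_auc <- function(score, positive) {
  pos <- which(positive); neg <- which(!positive)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  as.numeric(tot) / (length(pos) * length(neg))
}

# leave-one-out cGHD of every node, by brute-force recomputation
oracle_loo_cghd <- function(A, B) {
  n <- nrow(A)
  vapply(seq_len(n), function(i)
    oracle_cghd(A[-i, -i, drop = FALSE], B[-i, -i, drop = FALSE]), 0)
}
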