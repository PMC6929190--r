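# Shared fixtures and independent oracles for the test suite.

# Seeded Gaussian recovery instance: unit-norm-column A (m x n) and an
# exactly k-sparse theta with magnitudes in [0.5, 1.5].
sparse_instance <- function(m, n, k, seed) {
  set.seed(seed)
  A <- matrix(rnorm(m * n), m, n)
  A <- sweep(A, 2L, sqrt(colSums(A^2)), `/`)
  theta <- numeric(n)
  supp <- sample.int(n, k)
  theta[supp] <- runif(k, 0.5, 1.5) * sample(c(-1, 1), k, replace = TRUE)
  list(A = A, theta = theta, support = sort(supp), y = drop(A %*% theta))
}

# Brute-force oracle: the minimum least-squares residual norm over all
# size-k column subsets (exhaustive enumeration; only viable for tiny n).
best_subset_residual <- function(y, A, k) {
  subsets <- combn(ncol(A), k, simplify = FALSE)
  best <- Inf
  for (s in subsets) {
    As <- A[, s, drop = FALSE]
    coef <- qr.coef(qr(As), y)
    r <- y - drop(As %*% coef)
    best <- min(best, sqrt(sum(r^2)))
  }
  best
}

# Greedy bipartite matching of true dictionary atoms to learned atoms by
# absolute cosine similarity; returns the number matched above `thresh`.
match_atoms <- function(true_atoms, learned_atoms, thresh = 0.99) {
  G <- abs(crossprod(true_atoms, learned_atoms))
  used <- integer(0)
  matched <- 0L
  for (i in order(-apply(G, 1L, max))) {
    avail <- setdiff(seq_len(ncol(G)), used)
    j <- avail[which.max(G[i, avail])]
    if (G[i, j] > thresh) {
      matched <- matched + 1L
      used <- c(used, j)
    }
  }
  matched
}

# Exactly k-sparse corpus over a known random dictionary, for K-SVD
# dictionary-recovery experiments.
dictionary_recovery_setup <- function(n = 64, K = 32, k = 3, m = 400,
                                      seed = 5) {
  set.seed(seed)
  true_atoms <- matrix(rnorm(n * K), n, K)
  true_atoms <- sweep(true_atoms, 2L, sqrt(colSums(true_atoms^2)), `/`)
  segs <- sapply(seq_len(m), function(j) {
    th <- numeric(K)
    th[sample.int(K, k)] <- runif(k, 0.5, 1.5) * sample(c(-1, 1), k, TRUE)
    drop(true_atoms %*% th)
  })
  list(true_atoms = true_atoms,
       corpus = segment_corpus(as.numeric(segs), n))
}
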