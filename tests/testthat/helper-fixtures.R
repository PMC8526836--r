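# shared fixtures and small oracles, built in code

# timeseries with exact pairwise correlations: rows are linear combinations
# of an orthonormal, zero-mean basis
orthonormal_basis <- function(n_vec, len, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(len * (n_vec + 1)), len, n_vec + 1)
  Q <- qr.Q(qr(cbind(1, M)))[, -1, drop = FALSE]  # orthogonal to intercept
  t(Q[, seq_len(n_vec), drop = FALSE])            # rows: unit norm, mean 0
}

# brute-force mean Fisher-z connectivity per voxel (double loop)
gc_oracle <- function(data, coords = NULL, radius = 0) {
  n <- nrow(data)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- c()
    for (j in seq_len(n)) {
      if (i == j) next
      if (radius > 0 && sqrt(sum((coords[i, ] - coords[j, ])^2)) <= radius) next
      r <- cor(data[i, ], data[j, ])
      r <- max(min(r, 1 - 1e-7), -(1 - 1e-7))
      acc <- c(acc, atanh(r))
    }
    out[i] <- if (length(acc)) mean(acc) else NA_real_
  }
  out
}

# exhaustive hypergeometric upper tail: enumerate every possible draw of
# size_A from a universe of N with size_B marked, count overlaps >= k
hypergeom_oracle <- function(k, size_A, size_B, N) {
  if (k == 0) return(1)
  draws <- utils::combn(N, size_A)
  marked <- seq_len(size_B)
  mean(apply(draws, 2, function(d) sum(d %in% marked) >= k))
}

# do two labelings define the same partition?
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

tiny_connectome <- function(n = 6, seed = 1) {
  normalize_connectome(make_connectome(n, density = 0.8, seed = seed))
}
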