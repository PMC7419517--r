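# Small deterministic fixtures built in code.

# standardized genotypes + frequencies for a given size
std_fixture <- function(n, m, seed = 1, maf = c(0.05, 0.5)) {
  g <- sim_genotypes(n, m, maf = maf, seed = seed)
  freq <- colMeans(g$counts) / 2
  list(counts = g$counts, freq = freq, snps = g$snps,
       X = standardize_genotypes(g$counts, freq))
}

# exact randomized-system ingredients via dense products (independent oracle)
dense_T <- function(X, members) {
  K <- length(members)
  grms <- lapply(members, function(s) tcrossprod(X[, s, drop = FALSE]) / length(s))
  Tm <- matrix(0, K, K)
  for (k in seq_len(K)) for (l in seq_len(K)) Tm[k, l] <- sum(grms[[k]] * grms[[l]])
  Tm
}

single_comp <- function(m) annotation_set(list(seq_len(m)), M = m, mode = "disjoint")
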