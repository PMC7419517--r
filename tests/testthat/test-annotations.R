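test_that("LD scores: self-correlation, duplicates, and cross-chromosome exclusion", {
  set.seed(2)
  n <- 200
  x <- standardize_genotypes(matrix(rbinom(n, 2, 0.3), n, 1), 0.3)
  X <- cbind(x, x, standardize_genotypes(matrix(rbinom(n, 2, 0.4), n, 1), 0.4))
  bp <- c(100L, 200L, 500L)
  chrom <- c("1", "1", "2")
  sc <- ld_scores(X, bp, chrom, window_bp = 1e6)
  expect_equal(sc[1], 2)           # duplicated SNP pair: r^2 = 1 plus self
  expect_equal(sc[2], 2)
  expect_equal(sc[3], 1)           # alone on its chromosome: self only
})

test_that("LD scores match the dense all-pairs oracle within the window", {
  fx <- std_fixture(300, 150, seed = 8)
  bp <- fx$snps$bp
  sc <- ld_scores(fx$X, bp, window_bp = 20000, chunk = 37)
  R2 <- (crossprod(fx$X) / 300)^2
  mask <- abs(outer(bp, bp, `-`)) <= 20000
  expect_lt(max(abs(sc - colSums(R2 * mask))), 1e-10)
  expect_true(all(sc >= 1))
})

test_that("independent SNPs have LD scores near 1", {
  fx <- std_fixture(2000, 200, seed = 9)
  sc <- ld_scores(fx$X, fx$snps$bp, window_bp = 1e6)
  # each neighbor contributes r^2 with mean ~ 1/(N-1) under independence
  expect_lt(abs(mean(sc) - (1 + 199 / 1999)), 0.02)
})

test_that("MAF x LD partition reproduces the standard binning schemes", {
  set.seed(3)
  freq <- runif(4000, 0.01, 0.5)
  sc <- 1 + rchisq(4000, df = 2)
  part <- maf_ld_partition(freq, sc, maf_breaks = 0.05, n_score_bins = 4)
  expect_equal(part$K, 8L)
  expect_equal(sum(part$sizes), 4000L)
  expect_equal(sort(unique(part$assign)), 1:8)

  # the 6-MAF x 4-LD scheme conserves the partition
  p24 <- suppressMessages(maf_ld_partition(
    freq, sc, maf_breaks = c(0.01, 0.02, 0.03, 0.04, 0.05), n_score_bins = 4))
  expect_equal(sum(p24$sizes), 4000L)
  expect_true(all(p24$sizes >= 1))

  # distinct scores, one MAF bin, quartiles: one SNP per bin
  p4 <- maf_ld_partition(c(0.1, 0.2, 0.3, 0.4), c(1, 2, 3, 4),
                         maf_breaks = numeric(), n_score_bins = 4)
  expect_equal(unname(p4$sizes), rep(1L, 4))
  # ties break to the lower bin deterministically
  expect_identical(
    maf_ld_partition(freq, sc, 0.05, 4)$assign,
    maf_ld_partition(freq, sc, 0.05, 4)$assign)
})

test_that("empty bins are dropped with a remap", {
  freq <- runif(100, 0.2, 0.5)           # nothing below 0.05
  expect_message(
    p <- maf_ld_partition(freq, seq_len(100), maf_breaks = 0.05, n_score_bins = 2),
    "empty")
  expect_equal(p$K, 2L)
  expect_equal(sum(p$sizes), 100L)
})

test_that("annotation files load in binary and continuous modes", {
  set.seed(4)
  A <- matrix(rbinom(50 * 28, 1, 0.3), 50, 28)
  A[rowSums(A) == 0, 1] <- 1
  p <- tempfile()
  write.table(A, p, row.names = FALSE, col.names = FALSE)
  ann <- read_annotations(p, "binary", M = 50)
  expect_equal(ann$K, 28L)
  expect_equal(ann$mode, "overlapping")
  expect_equal(unname(ann$sizes), unname(colSums(A)))

  # all-ones column reduces to the single-component model
  write.table(matrix(1, 50, 1), p, row.names = FALSE, col.names = FALSE)
  a1 <- read_annotations(p, "binary", M = 50)
  expect_equal(a1$K, 1L)
  expect_equal(a1$members[[1]], 1:50)

  # negative continuous weight rejected
  bad <- matrix(abs(rnorm(50)), 50, 1)
  bad[7] <- -0.5
  write.table(bad, p, row.names = FALSE, col.names = FALSE)
  expect_error(read_annotations(p, "continuous", M = 50), "negative")

  # row-count mismatch
  write.table(matrix(1, 49, 1), p, row.names = FALSE, col.names = FALSE)
  expect_error(read_annotations(p, "binary", M = 50), "match")
})

test_that("continuous weights scale standardized columns by sqrt(a)", {
  fx <- std_fixture(40, 6, seed = 6)
  w <- c(1, 4, 0.25, 2, 1, 9)
  ann <- annotation_set(list(1:6), M = 6, mode = "continuous", weights = list(w))
  out <- apply_continuous_weights(fx$X, 1:6, ann, 1)
  expect_equal(out$X, sweep(fx$X, 2, sqrt(w), `*`))
  # identity weights leave the block unchanged
  ann1 <- annotation_set(list(1:6), M = 6, mode = "continuous",
                         weights = list(rep(1, 6)))
  expect_equal(apply_continuous_weights(fx$X, 1:6, ann1, 1)$X, fx$X)
  # weighted GRM equals X diag(a) X' / M by direct multiplication
  G <- tcrossprod(out$X) / 6
  expect_equal(G, fx$X %*% diag(w) %*% t(fx$X) / 6, tolerance = 1e-12)
})

test_that("disjoint annotation sets must partition the SNPs", {
  expect_error(annotation_set(list(1:3, 3:5), M = 5, mode = "disjoint"), "partition")
  expect_error(annotation_set(list(1:3, integer(0)), M = 5, mode = "disjoint"),
               "at least one SNP")
  expect_error(annotation_set(list(1:3), M = 3, mode = "continuous",
                              weights = list(c(1, -1, 1))), "negative")
})
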