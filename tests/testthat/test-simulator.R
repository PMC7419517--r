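test_that("independent genotypes match their target frequencies", {
  g <- sim_genotypes(5000, 100, seed = 61)
  obs <- colMeans(g$counts) / 2
  se <- sqrt(g$freq * (1 - g$freq) / (2 * 5000))
  expect_lt(max(abs(obs - g$freq) / se), 5)
  expect_true(all(g$counts %in% 0:2))
  expect_equal(g$snps$bp, 1000L * 1:100)   # 1 kb spacing on one chromosome
})

test_that("blockwise AR genotypes show within-block but not cross-block LD", {
  g <- sim_genotypes(1500, 100, ld = list(rho = 0.9, block_len = 25), seed = 62)
  f <- colMeans(g$counts) / 2
  # marginal frequencies preserved by thresholding
  expect_lt(max(abs(f - g$freq)), 5 * sqrt(0.25 / (2 * 1500)) + 0.03)
  X <- standardize_genotypes(g$counts, f)
  R2 <- (crossprod(X) / 1500)^2
  blk <- rep(1:4, each = 25)
  same <- outer(blk, blk, `==`) & upper.tri(R2)
  adj <- abs(outer(1:100, 1:100, `-`)) == 1 & same
  expect_gt(mean(R2[adj]), mean(R2[!same & upper.tri(R2)]) * 5)
  # rho = 0 reduces to the independent sampler
  g0 <- sim_genotypes(1500, 60, ld = list(rho = 0, block_len = 25), seed = 63)
  X0 <- standardize_genotypes(g0$counts, colMeans(g0$counts) / 2)
  R20 <- (crossprod(X0) / 1500)^2
  expect_lt(abs(mean(R20[upper.tri(R20)]) - 1 / 1499), 3e-4)
})

test_that("causal selection respects the fraction and MAF window", {
  freq <- runif(10000, 0.01, 0.5)
  m_all <- sim_causal(freq, p = 1, window = c(0, 0.5), seed = 64)
  expect_true(all(m_all))
  m1 <- sim_causal(freq, p = 0.01, window = c(0, 0.5), seed = 64)
  expect_equal(sum(m1), 100)
  mw <- sim_causal(freq, p = 0.005, window = c(0.01, 0.05), seed = 65)
  expect_true(all(freq[mw] >= 0.01 & freq[mw] <= 0.05))
  expect_error(sim_causal(freq, p = 1, window = c(0.49999, 0.5)), "window")
})

test_that("architecture variances follow the coupling model", {
  fx <- std_fixture(200, 50, seed = 66)
  # flat architecture: every SNP gets h2 / M
  ph <- sim_phenotype(fx$X, fx$freq, h2 = 0.3, a = 0, b = 0, seed = 67)
  expect_equal(ph$truth$sigma2_m, rep(0.3 / 50, 50))
  # MAF coupling: variance ratios follow [f(1-f)]^a
  ph2 <- sim_phenotype(fx$X, fx$freq, h2 = 0.3, a = 0.75, seed = 67)
  v <- ph2$truth$sigma2_m
  het <- fx$freq * (1 - fx$freq)
  expect_equal(v[1] / v[2], (het[1] / het[2])^0.75, tolerance = 1e-10)
  expect_equal(sum(v), 0.3)
  # weight coupling
  w <- runif(50, 0.5, 2)
  ph3 <- sim_phenotype(fx$X, fx$freq, h2 = 0.3, b = 1, weights = w, seed = 67)
  expect_equal(ph3$truth$sigma2_m / sum(ph3$truth$sigma2_m), w / sum(w),
               tolerance = 1e-10)
  expect_error(sim_phenotype(fx$X, fx$freq, h2 = 1.2), "h2")
})

test_that("phenotype variance is calibrated to 1 in expectation", {
  fx <- std_fixture(400, 300, seed = 68)
  y0 <- sim_phenotype(fx$X, fx$freq, h2 = 0, seed = 69)$y
  expect_lt(abs(var(y0) - 1), 0.15)
  Y <- sim_phenotype(fx$X, fx$freq, h2 = 0.6, reps = 50, seed = 70)$y
  expect_lt(abs(mean(apply(Y, 2, var)) - 1), 0.1)
})

test_that("per-component truth decomposes total heritability over a partition", {
  fx <- std_fixture(100, 60, seed = 71)
  mask <- sim_causal(fx$freq, 0.5, seed = 72)
  ph <- sim_phenotype(fx$X, fx$freq, h2 = 0.4, causal = mask, a = 0.75, seed = 73)
  ann <- annotation_set(split(1:60, rep(1:4, 15)), M = 60)
  h2k <- ph$truth$h2_by(ann)
  expect_equal(sum(h2k), 0.4, tolerance = 1e-10)
  expect_true(all(ph$truth$sigma2_m[!mask] == 0))
})

test_that("fixtures round-trip through PLINK with correct metadata", {
  g <- sim_genotypes(9, 14, seed = 74)
  ph <- list(y = rnorm(9))
  prefix <- file.path(tempdir(), "fixt")
  write_fixture(g, ph$y, prefix,
                truth = list(sigma2_m = rep(1 / 14, 14), causal = rep(TRUE, 14)))
  magic <- readBin(paste0(prefix, ".bed"), "raw", 3)
  expect_identical(magic, as.raw(c(0x6c, 0x1b, 0x01)))
  expect_equal(nrow(read_fam(prefix)), 9)
  expect_equal(nrow(read_bim(prefix)), 14)
  src <- plink_source(prefix)
  got <- src$next_block()
  expect_identical(got$counts, matrix(as.integer(g$counts), 9, 14))
  expect_equal(read_pheno(paste0(prefix, ".pheno"))[[3]], ph$y, tolerance = 1e-6)
  tr <- read.table(paste0(prefix, ".truth.tsv"), header = TRUE)
  expect_equal(nrow(tr), 14)
})

test_that("the master seed splits into reproducible independent streams", {
  s1 <- sim_dataset(50, 40, seed = 99)
  s2 <- sim_dataset(50, 40, seed = 99)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$y, s2$y)
  s3 <- sim_dataset(50, 40, seed = 100)
  expect_false(identical(s1$y, s3$y))
  expect_identical(seed_streams(7, 4), seed_streams(7, 4))
})
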