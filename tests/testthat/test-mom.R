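test_that("the random sketch is reproducible and standard normal", {
  Z1 <- rhe_sketch(50, 3, seed = 42)
  Z2 <- rhe_sketch(50, 3, seed = 42)
  expect_identical(Z1, Z2)
  expect_equal(ncol(rhe_sketch(5)), 10)   # default B = 10
  Z <- rhe_sketch(1e5, 4, seed = 1)
  expect_lt(max(abs(colMeans(Z))), 0.05)
  expect_lt(max(abs(crossprod(Z) / 1e5 - diag(4))), 0.05)
})

test_that("accumulated sketch images equal the dense product", {
  fx <- std_fixture(50, 30, seed = 21)
  z <- rhe_sketch(50, 1, seed = 3)
  acc <- rhe_accumulate(fx$X, single_comp(30), z, rep(0, 50),
                        n_blocks = 2, block_size = 7)
  v <- Reduce(`+`, acc$images)
  expect_equal(v, fx$X %*% crossprod(fx$X, z), tolerance = 1e-10)
  # null phenotype: all quadratic partials zero
  expect_true(all(acc$quad == 0))
  expect_equal(unname(acc$yty), 0)
})

test_that("accumulated moments are invariant to the streaming block size", {
  fx <- std_fixture(120, 90, seed = 22)
  ann <- annotation_set(split(1:90, rep(1:3, length.out = 90)), M = 90)
  Z <- rhe_sketch(120, 5, seed = 9)
  y <- rnorm(120)
  sys <- lapply(c(13, 90, 1000), function(bs) {
    rhe_system(rhe_accumulate(fx$X, ann, Z, y, n_blocks = 4, block_size = bs))
  })
  for (s in sys[-1]) {
    expect_equal(s$T_hat, sys[[1]]$T_hat, tolerance = 1e-8)
    expect_equal(s$c_mat, sys[[1]]$c_mat, tolerance = 1e-8)
  }
})

test_that("the Hutchinson trace estimate is unbiased for tr(K_k K_l)", {
  fx <- std_fixture(50, 30, seed = 23)
  members <- split(1:30, rep(1:3, each = 10))
  ann <- annotation_set(members, M = 30)
  T_exact <- dense_T(fx$X, members)
  B <- 1000
  Z <- rhe_sketch(50, B, seed = 31)
  acc <- rhe_accumulate(fx$X, ann, Z, rep(0, 50), n_blocks = 2)
  # per-vector samples of the k = l = 1 entry give a Monte-Carlo SE
  V <- Reduce(`+`, acc$images)
  K <- 3
  per_vec <- vapply(seq_len(B), function(b) {
    sum(V[, (b - 1) * K + 1]^2) / (10 * 10)
  }, numeric(1))
  mc_se <- sd(per_vec) / sqrt(B)
  expect_lt(abs(mean(per_vec) - T_exact[1, 1]), 3 * mc_se)
  # full matrix close to exact at B = 1000
  That <- rhe_system(acc)$T_hat
  expect_lt(max(abs(That - T_exact) / abs(T_exact)), 0.25)
})

test_that("duplicated components give identical trace entries", {
  fx <- std_fixture(40, 20, seed = 24)
  ann <- annotation_set(list(1:20, 1:20), M = 20, mode = "overlapping")
  Z <- rhe_sketch(40, 3, seed = 5)
  That <- rhe_system(rhe_accumulate(fx$X, ann, Z, rnorm(40), n_blocks = 2))$T_hat
  expect_equal(That[1, 1], That[1, 2])
  expect_equal(That[1, 1], That[2, 2])
})

test_that("quadratic forms match the dense GRM oracle", {
  fx <- std_fixture(50, 30, seed = 25)
  members <- split(1:30, rep(1:2, each = 15))
  ann <- annotation_set(members, M = 30)
  y <- fx$X[, 4]                      # a standardized SNP column in component 1
  Z <- rhe_sketch(50, 2, seed = 6)
  sys <- rhe_system(rhe_accumulate(fx$X, ann, Z, y, n_blocks = 2))
  for (k in 1:2) {
    Kk <- tcrossprod(fx$X[, members[[k]], drop = FALSE]) / 15
    expect_equal(sys$c_mat[k, 1], drop(crossprod(y, Kk %*% y)), tolerance = 1e-10)
  }
})

test_that("the bordered system solves exactly and falls back gracefully", {
  # K = 1 bordered system [[3, 2], [2, 2]] x = (5, 3) by direct linear algebra
  sol <- vc_solve(matrix(3, 1, 1), 2, 5, 3)
  expect_equal(unname(drop(sol)),
               solve(matrix(c(3, 2, 2, 2), 2), c(5, 3)), tolerance = 1e-12)
  # duplicated component rows: singular, least-squares path with finite norm
  Td <- matrix(2, 2, 2)
  expect_warning(s2 <- vc_solve(Td, 1, c(1, 1), 1), "least squares")
  expect_true(all(is.finite(s2)))
})

test_that("heritability and enrichment summaries follow their definitions", {
  s <- vc_summary(c(1, 1), Mk = 10, M = 10)
  expect_equal(s$h2_total, 0.5)
  expect_equal(unname(s$enrichment), 1)

  s2 <- vc_summary(c(0.3, 0.2, 0.5), Mk = c(10, 90), M = 100)
  expect_equal(s2$h2_total, 0.5)
  expect_equal(unname(s2$h2_comp), c(0.3, 0.2))
  expect_equal(unname(s2$enrichment[1]), (0.3 / 0.5) / 0.1)  # = 6

  # overlapping: two annotations over the same 3 SNPs; expanding the
  # per-SNP-variance sum by hand: each SNP carries s1/3 + s2/3
  ov <- matrix(3, 2, 2)
  so <- vc_summary(c(0.1, 0.1, 0.8), Mk = c(3, 3), M = 3, mode = "overlapping",
                   overlap = ov)
  expect_equal(unname(so$h2_comp),
               rep(3 * (0.1 / 3 + 0.1 / 3), 2) / (0.1 + 0.1 + 0.8))

  # zero heritability: enrichment undefined
  expect_true(all(is.na(vc_summary(c(0, 0.7), Mk = 5, M = 5)$enrichment)))
})

test_that("disjoint enrichment obeys the conservation identity", {
  fx <- std_fixture(150, 60, seed = 26)
  ann <- annotation_set(split(1:60, rep(1:4, length.out = 60)), M = 60)
  y <- rnorm(150)
  fit <- rhe_mc(fx$counts, y, partition = ann, n_blocks = 5, seed = 2, qc = FALSE)
  expect_equal(sum(fit$Mk / fit$M * fit$enrichment), 1, tolerance = 1e-8)
})

test_that("covariate projection centers, absorbs, and counts rank", {
  y <- rnorm(30) + 5
  pc <- project_covariates(y)
  expect_equal(pc$y, y - mean(y))
  expect_equal(pc$n_eff, 29)
  # duplicated column dropped with a warning
  W <- cbind(1:30, 1:30)
  expect_warning(pc2 <- project_covariates(y, W), "rank")
  expect_equal(pc2$n_eff, 28)
  # a covariate equal to y absorbs everything
  fx <- std_fixture(100, 40, seed = 27)
  yy <- rnorm(100)
  fit <- rhe_mc(fx$counts, yy, covariates = cbind(rnorm(100), yy),
                partition = single_comp(40), n_blocks = 4, seed = 3, qc = FALSE)
  # everything is absorbed: all variance components collapse to numerical zero
  expect_lt(max(abs(fit$sigma2)), 1e-10)
})

test_that("null covariates leave the heritability estimate unchanged within noise", {
  set.seed(28)
  n <- 500
  fx <- std_fixture(n, 300, seed = 28)
  reps <- 30
  d <- replicate(reps, {
    y <- sim_phenotype(fx$X, fx$freq, 0.5)$y
    f0 <- rhe_mc(fx$counts, y, partition = single_comp(300), n_blocks = 10,
                 seed = 4, qc = FALSE)
    f1 <- rhe_mc(fx$counts, y, covariates = matrix(rnorm(n * 5), n),
                 partition = single_comp(300), n_blocks = 10, seed = 4, qc = FALSE)
    f1$h2_total - f0$h2_total
  })
  expect_lt(abs(mean(d)), 2 * sd(d) / sqrt(reps) + 0.01)
})

test_that("estimates are invariant to phenotype scale", {
  fx <- std_fixture(200, 80, seed = 29)
  y <- sim_phenotype(fx$X, fx$freq, 0.4)$y
  f1 <- rhe_mc(fx$counts, y, partition = single_comp(80), n_blocks = 5,
               seed = 5, qc = FALSE)
  f2 <- rhe_mc(fx$counts, 3 * y, partition = single_comp(80), n_blocks = 5,
               seed = 5, qc = FALSE)
  expect_equal(f2$h2_total, f1$h2_total, tolerance = 1e-10)
  expect_equal(f2$enrichment, f1$enrichment, tolerance = 1e-10)
  expect_equal(unname(f2$sigma2), unname(9 * f1$sigma2), tolerance = 1e-8)
})

test_that("continuous annotations with unit weights reproduce binary moments", {
  fx <- std_fixture(80, 40, seed = 30)
  members <- list(1:20, 21:40)
  annB <- annotation_set(members, M = 40)
  annC <- annotation_set(members, M = 40, mode = "continuous",
                         weights = lapply(members, function(s) rep(1, length(s))))
  Z <- rhe_sketch(80, 4, seed = 7)
  y <- rnorm(80)
  sB <- rhe_system(rhe_accumulate(fx$X, annB, Z, y, n_blocks = 4))
  sC <- rhe_system(rhe_accumulate(fx$X, annC, Z, y, n_blocks = 4))
  expect_equal(sB$T_hat, sC$T_hat, tolerance = 1e-10)
  expect_equal(sB$c_mat, sC$c_mat, tolerance = 1e-10)
})
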