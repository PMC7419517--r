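# Replication-style simulation studies: each driver simulates genotypes and
# MAF/LD-architecture phenotypes, runs the randomized estimator under the
# standard binning schemes, and summarizes accuracy or calibration. Phenotype
# replicates are batched against a shared accumulator (the sketch images
# depend only on genotypes and sketch, not on y), with the sketch refreshed
# per replicate group and genotypes redrawn across a few independent draws,
# so replicate averages integrate over phenotype, sketch and genotype noise.

.center_cols <- function(A) sweep(A, 2L, colMeans(A))

# enrichment matrix across delete-block fits: rows j, cols components
.enr_from_sigma <- function(S, Mk, M) {
  # S: J x (K+1); Mk: J x K (or vector); M: length-J (or scalar)
  K <- ncol(S) - 1L
  gs <- rowSums(S[, seq_len(K), drop = FALSE])
  denom <- gs + S[, K + 1L]
  h2c <- S[, seq_len(K), drop = FALSE] / denom
  h2 <- gs / denom
  (h2c / h2) / (Mk / M)
}

#' Genome-wide heritability bias study
#'
#' Simulates independent genotypes, draws phenotypes under each requested
#' MAF/LD-coupled architecture `(a, b)` (the weight entering the `b` coupling
#' is the inverse in-sample LD score, a synthetic stand-in for LDAK weights),
#' fits the randomized estimator with a MAF x LD-score-quantile partition,
#' and reports the relative bias of the genome-wide heritability estimate per
#' architecture.
#'
#' @param n,m Individuals and SNPs per genotype draw.
#' @param h2 True SNP heritability.
#' @param archs data.frame with columns `a`, `b` (one row per architecture).
#' @param reps_per_arch Minimum phenotype replicates per architecture.
#' @param geno_draws Independent genotype draws to average over.
#' @param groups_per_draw Independent B-vector sketches per genotype draw;
#'   replicates within a draw are spread across them, so the sketch noise of
#'   the randomized trace (the dominant noise in the bias estimate at these
#'   sizes) is averaged over `geno_draws * groups_per_draw` draws.
#' @param causal_frac,causal_window Causal fraction and MAF window (the
#'   causal mask is shared across architectures within a genotype draw).
#' @param maf_breaks,ld_quantiles,ld_window_bp Partition scheme.
#' @param B Sketch vectors per fit.
#' @param seed Master seed.
#' @return List with `per_arch` (mean estimate, SD, relative bias in percent
#'   per architecture), `max_abs_rel_bias_pct`, and the per-replicate
#'   estimates.
#' @details Within a genotype draw, the architectures share the causal mask
#'   and the base Gaussian draws of effects and noise (common random
#'   numbers): each architecture only rescales the per-SNP effect SDs. Each
#'   per-architecture bias estimate is unchanged in expectation; the shared
#'   noise merely correlates the architectures' Monte-Carlo errors, which
#'   sharpens the max-over-architectures summary. All B-vector sketch groups
#'   of a draw are stacked into a single streaming pass (the accumulator's
#'   images are linear in the probe vectors), and each group's trace matrix
#'   is assembled from its own B columns.
#' @export
study_h2_bias <- function(n = 2000, m = 5000, h2 = 0.5,
                          archs = data.frame(a = c(0, 0.75, 0, 0.75),
                                             b = c(0, 0, 1, 1)),
                          reps_per_arch = 4000, geno_draws = 8,
                          groups_per_draw = 100, causal_frac = 1,
                          causal_window = c(0, 0.5), maf_breaks = 0.05,
                          ld_quantiles = 4L, ld_window_bp = 1e6, B = 10L,
                          seed = 1L) {
  n_arch <- nrow(archs)
  r_draw <- ceiling(reps_per_arch / geno_draws)
  G <- as.integer(groups_per_draw)
  dseeds <- seed_streams(seed, geno_draws)
  h2_est <- rep(list(numeric(0)), n_arch)
  for (d in seq_len(geno_draws)) {
    ds <- seed_streams(dseeds[d], 5L)
    g <- sim_genotypes(n, m, seed = ds[1])
    freq <- colMeans(g$counts) / 2
    X <- standardize_genotypes(g$counts, freq)
    sc <- if (ld_quantiles > 1L) {
      ld_scores(X, g$snps$bp, g$snps$chrom, ld_window_bp)
    } else NULL
    part <- suppressMessages(
      maf_ld_partition(freq, sc, maf_breaks, ld_quantiles))
    w <- if (!is.null(sc)) 1 / sc else rep(1, m)
    K <- part$K
    mask <- sim_causal(freq, causal_frac, causal_window, seed = ds[2])
    cset <- which(mask)
    s2m <- lapply(seq_len(n_arch), function(i) {
      raw <- w[cset]^archs$b[i] * (freq[cset] * (1 - freq[cset]))^archs$a[i]
      raw * (h2 / sum(raw))
    })
    # stacked sketch: G groups of B centered probe vectors in one pass
    Z <- .center_cols(.with_seed(ds[3], matrix(stats::rnorm(n * B * G), n)))
    # common random numbers: architectures share base effect and noise draws
    Bz <- .with_seed(ds[4], matrix(stats::rnorm(length(cset) * r_draw),
                                   length(cset)))
    E <- .with_seed(ds[5], matrix(stats::rnorm(n * r_draw), n)) * sqrt(1 - h2)
    Y <- matrix(0, n, r_draw * n_arch)
    for (i in seq_len(n_arch)) {
      Y[, (i - 1L) * r_draw + seq_len(r_draw)] <-
        X[, cset, drop = FALSE] %*% (Bz * sqrt(s2m[[i]])) + E
    }
    Y <- .center_cols(Y)
    acc <- rhe_accumulate(X, part, Z, Y, n_blocks = 2L)
    V <- Reduce(`+`, acc$images)
    Mk <- rowSums(acc$counts)
    cmat <- apply(acc$quad, c(1, 3), sum) / Mk
    grp_of_rep <- rep_len(seq_len(G), r_draw)
    for (gi in seq_len(G)) {
      cols <- (gi - 1L) * K * B + seq_len(K * B)
      Tg <- .gram_to_T(crossprod(V[, cols, drop = FALSE]), K, B, Mk)
      rsel <- which(grp_of_rep == gi)
      if (!length(rsel)) next
      sel <- as.vector(outer(rsel, (seq_len(n_arch) - 1L) * r_draw, `+`))
      sol <- vc_solve(Tg, n - 1L, cmat[, sel, drop = FALSE], acc$yty[sel])
      h2col <- colSums(sol[seq_len(K), , drop = FALSE]) / colSums(sol)
      for (i in seq_len(n_arch)) {
        ii <- seq_along(rsel) + (i - 1L) * length(rsel)
        h2_est[[i]] <- c(h2_est[[i]], h2col[ii])
      }
    }
  }
  per_arch <- cbind(archs, data.frame(
    mean_h2 = vapply(h2_est, mean, numeric(1)),
    sd_h2 = vapply(h2_est, stats::sd, numeric(1)),
    n_reps = vapply(h2_est, length, numeric(1))))
  per_arch$rel_bias_pct <- 100 * (per_arch$mean_h2 - h2) / h2
  list(per_arch = per_arch,
       max_abs_rel_bias_pct = max(abs(per_arch$rel_bias_pct)),
       h2_true = h2, estimates = h2_est)
}

#' Enrichment Z-test calibration study
#'
#' Null-enrichment simulation: a flat infinitesimal architecture (`a = b = 0`,
#' all SNPs causal) makes every bin's true enrichment 1. Each replicate is fit
#' with the full jackknife, and the two-sided Z-test of `enrichment = 1` in a
#' designated bin is recorded at level `alpha`. A calibrated test rejects at
#' rate `alpha`.
#'
#' @inheritParams study_h2_bias
#' @param reps Phenotype replicates.
#' @param groups Sketch-refresh groups.
#' @param n_blocks Jackknife blocks per fit.
#' @param bin Component whose enrichment test is scored.
#' @param alpha Test level.
#' @return List with `rejection_rate_pct`, per-replicate `z`, and the
#'   binomial 95\% acceptance band around `alpha` for this replicate count.
#' @export
study_enrichment_calibration <- function(n = 4000, m = 8000, h2 = 0.5,
                                         reps = 400, groups = 20,
                                         maf_breaks = 0.05, ld_quantiles = 4L,
                                         ld_window_bp = 1e6, B = 10L,
                                         n_blocks = 100L, bin = 1L,
                                         alpha = 0.05, seed = 1L) {
  ss <- seed_streams(seed, 1L + 2L * groups)
  g <- sim_genotypes(n, m, seed = ss[1])
  freq <- colMeans(g$counts) / 2
  X <- standardize_genotypes(g$counts, freq)
  sc <- ld_scores(X, g$snps$bp, g$snps$chrom, ld_window_bp)
  part <- suppressMessages(maf_ld_partition(freq, sc, maf_breaks, ld_quantiles))
  K <- part$K
  r_cell <- ceiling(reps / groups)
  zs <- numeric(0)
  for (gi in seq_len(groups)) {
    Z <- .center_cols(rhe_sketch(n, B, seed = ss[1L + gi]))
    Y <- .center_cols(matrix(
      sim_phenotype(X, freq, h2, reps = r_cell, seed = ss[1L + groups + gi])$y,
      nrow = n))
    acc <- rhe_accumulate(X, part, Z, Y, n_blocks = n_blocks)
    jsys <- rhe_jackknife_systems(acc)
    sys <- rhe_system(acc)
    sol <- vc_solve(sys$T_hat, n - 1L, sys$c_mat, sys$yty)
    deletes <- rhe_delete_fits(acc, systems = jsys)
    Mk_j <- t(vapply(jsys, function(s) s$Mk, numeric(K)))      # J x K
    M_j <- acc$M - colSums(acc$counts)                          # length J
    Mk_full <- rowSums(acc$counts)
    for (r in seq_len(r_cell)) {
      e_full <- .enr_from_sigma(matrix(sol[, r], 1L), Mk_full, acc$M)[bin]
      e_del <- .enr_from_sigma(deletes[, , r], Mk_j, M_j)
      se <- jackknife_se(e_del)[bin]
      zs <- c(zs, enrichment_test(e_full, se)$z)
    }
  }
  rate <- mean(abs(zs) > stats::qnorm(1 - alpha / 2))
  band <- alpha + c(-1, 1) * 1.96 * sqrt(alpha * (1 - alpha) / length(zs))
  list(rejection_rate_pct = 100 * rate, z = zs, n_reps = length(zs),
       band_pct = 100 * band)
}

#' Partitioning specificity study
#'
#' Causal variants are confined to one MAF window; components whose SNPs are
#' all non-causal should attract (close to) zero heritability. Reports the
#' mean estimated heritability aggregated over the non-causal components, as
#' a percentage of the true total heritability.
#'
#' @inheritParams study_h2_bias
#' @param reps Minimum total phenotype replicates.
#' @return List with `noncausal_bias_pct` (signed mean, in percent of true
#'   h2), `abs_noncausal_bias_pct`, and per-replicate values.
#' @export
study_partition_specificity <- function(n = 2000, m = 5000, h2 = 0.5,
                                        reps = 4000, geno_draws = 8,
                                        groups_per_draw = 125,
                                        causal_frac = 0.05,
                                        causal_window = c(0.01, 0.05),
                                        maf_breaks = 0.05, ld_quantiles = 4L,
                                        ld_window_bp = 1e6, B = 10L,
                                        seed = 1L) {
  r_draw <- ceiling(reps / geno_draws)
  G <- as.integer(groups_per_draw)
  dseeds <- seed_streams(seed, geno_draws)
  vals <- numeric(0)
  for (d in seq_len(geno_draws)) {
    ds <- seed_streams(dseeds[d], 4L)
    g <- sim_genotypes(n, m, seed = ds[1])
    freq <- colMeans(g$counts) / 2
    X <- standardize_genotypes(g$counts, freq)
    sc <- ld_scores(X, g$snps$bp, g$snps$chrom, ld_window_bp)
    part <- suppressMessages(maf_ld_partition(freq, sc, maf_breaks, ld_quantiles))
    K <- part$K
    mask <- sim_causal(freq, causal_frac, causal_window, seed = ds[2])
    noncausal <- which(vapply(part$members, function(s) !any(mask[s]), logical(1)))
    if (!length(noncausal)) stop("no non-causal components; widen the partition")
    Z <- .center_cols(.with_seed(ds[3], matrix(stats::rnorm(n * B * G), n)))
    Y <- .center_cols(matrix(
      sim_phenotype(X, freq, h2, mask, reps = r_draw, seed = ds[4])$y,
      nrow = n))
    acc <- rhe_accumulate(X, part, Z, Y, n_blocks = 2L)
    V <- Reduce(`+`, acc$images)
    Mk <- rowSums(acc$counts)
    cmat <- apply(acc$quad, c(1, 3), sum) / Mk
    grp_of_rep <- rep_len(seq_len(G), r_draw)
    for (gi in seq_len(G)) {
      cols <- (gi - 1L) * K * B + seq_len(K * B)
      Tg <- .gram_to_T(crossprod(V[, cols, drop = FALSE]), K, B, Mk)
      rsel <- which(grp_of_rep == gi)
      if (!length(rsel)) next
      sol <- vc_solve(Tg, n - 1L, cmat[, rsel, drop = FALSE], acc$yty[rsel])
      h2nc <- colSums(sol[noncausal, , drop = FALSE]) / colSums(sol)
      vals <- c(vals, h2nc)
    }
  }
  bias <- 100 * mean(vals) / h2
  list(noncausal_bias_pct = bias, abs_noncausal_bias_pct = abs(bias),
       values = vals, n_reps = length(vals))
}

#' Jackknife standard-error calibration study
#'
#' Compares the mean block-jackknife standard error of the genome-wide
#' heritability estimate with the empirical standard deviation of the
#' estimate across phenotype replicates; a calibrated jackknife gives a
#' ratio near 1.
#'
#' @inheritParams study_enrichment_calibration
#' @return List with `ratio` (mean jackknife SE / empirical SD), the
#'   per-replicate estimates and SEs.
#' @export
study_jackknife_calibration <- function(n = 2000, m = 5000, h2 = 0.5,
                                        reps = 200, groups = 10,
                                        maf_breaks = 0.05, ld_quantiles = 4L,
                                        ld_window_bp = 1e6, B = 10L,
                                        n_blocks = 100L, seed = 1L) {
  ss <- seed_streams(seed, 1L + 2L * groups)
  g <- sim_genotypes(n, m, seed = ss[1])
  freq <- colMeans(g$counts) / 2
  X <- standardize_genotypes(g$counts, freq)
  sc <- ld_scores(X, g$snps$bp, g$snps$chrom, ld_window_bp)
  part <- suppressMessages(maf_ld_partition(freq, sc, maf_breaks, ld_quantiles))
  K <- part$K
  r_cell <- ceiling(reps / groups)
  h2s <- ses <- numeric(0)
  for (gi in seq_len(groups)) {
    Z <- .center_cols(rhe_sketch(n, B, seed = ss[1L + gi]))
    Y <- .center_cols(matrix(
      sim_phenotype(X, freq, h2, reps = r_cell, seed = ss[1L + groups + gi])$y,
      nrow = n))
    acc <- rhe_accumulate(X, part, Z, Y, n_blocks = n_blocks)
    jsys <- rhe_jackknife_systems(acc)
    sys <- rhe_system(acc)
    sol <- vc_solve(sys$T_hat, n - 1L, sys$c_mat, sys$yty)
    deletes <- rhe_delete_fits(acc, systems = jsys)
    for (r in seq_len(r_cell)) {
      h2s <- c(h2s, sum(sol[seq_len(K), r]) / sum(sol[, r]))
      S <- deletes[, , r]
      h2_del <- rowSums(S[, seq_len(K), drop = FALSE]) / rowSums(S)
      ses <- c(ses, jackknife_se(matrix(h2_del, ncol = 1)))
    }
  }
  list(ratio = mean(ses) / stats::sd(h2s), h2 = h2s, se = ses,
       n_reps = length(h2s))
}
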