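#' Randomized multi-component Haseman-Elston regression
#'
#' Fits the variance-component model
#' `y = sum_k X_k beta_k + eps`, `beta_k ~ (0, sigma^2_k / M_k I)`,
#' `eps ~ (0, sigma^2_e I)` by method of moments, matching the empirical
#' covariance `y y'` to `sum_k sigma^2_k K_k + sigma^2_e I` where
#' `K_k = X_k X_k' / M_k` is the genetic relatedness matrix of component k.
#' The trace matrix `tr(K_k K_l)` of the normal equations is replaced by an
#' unbiased Hutchinson estimate from `B` Gaussian probe vectors, so the
#' genotypes are streamed exactly once. Standard errors for all reported
#' quantities come from a delete-one-SNP-block jackknife over `n_blocks`
#' contiguous blocks, and each component's enrichment is tested against the
#' null value 1.
#'
#' Components are defined either by a supplied [annotation_set()] (disjoint
#' bins, overlapping binary annotations, or continuous weights) or, by
#' default, by crossing MAF intervals with in-sample LD-score quantiles.
#' Variance-component estimates are not constrained to be non-negative.
#'
#' @param genotypes Allele-count matrix (individuals x SNPs, values 0/1/2/NA),
#'   a PLINK fileset prefix, or a genotype source.
#' @param phenotype Numeric vector aligned with the genotype rows, or the path
#'   of a `FID IID value` file (matched to the FAM by FID/IID intersection).
#' @param covariates Optional numeric matrix (or `FID IID ...` file path);
#'   an intercept is always included, so the phenotype is at least centered.
#' @param partition Optional [annotation_set()] over the QC-kept SNPs; when
#'   supplied, binning options are ignored.
#' @param maf_breaks Interior MAF breakpoints for binning (default 0.05,
#'   giving 2 MAF bins).
#' @param ld_quantiles Number of LD-score quantile bins (default 4).
#' @param ld_window_bp LD-score window (default 1 Mb).
#' @param scores Optional external per-SNP scores over all input SNPs (e.g.
#'   LDAK weights) used for binning instead of in-sample LD scores.
#' @param B Number of random sketch vectors (default 10).
#' @param n_blocks Number of jackknife blocks (default 100).
#' @param block_size SNPs per streaming block.
#' @param qc Apply SNP QC filters (missingness > `max_missing`,
#'   MAF < `min_maf`, HWE chi-square p < `hwe_alpha`)?
#' @param max_missing,min_maf,hwe_alpha QC thresholds.
#' @param seed Seed for the random sketch.
#' @param nonneg If TRUE, negative variance-component point estimates are
#'   truncated at zero post hoc (default FALSE: estimates reported as-is).
#' @param cond_tol Condition-number cutoff for the least-squares fallback.
#' @return An object of class `"rhe_mc"`; see [summary.rhe_mc()].
#' @examples
#' sim <- sim_dataset(n = 500, m = 800, h2 = 0.5, seed = 7)
#' fit <- rhe_mc(sim$counts, sim$y, maf_breaks = numeric(),
#'               ld_quantiles = 1, n_blocks = 10, seed = 7)
#' fit
#' @export
rhe_mc <- function(genotypes, phenotype, covariates = NULL, partition = NULL,
                   maf_breaks = 0.05, ld_quantiles = 4L, ld_window_bp = 1e6,
                   scores = NULL, B = 10L, n_blocks = 100L, block_size = 1000L,
                   qc = TRUE, max_missing = 0.01, min_maf = 0.01,
                   hwe_alpha = 1e-7, seed = 1L, nonneg = FALSE,
                   cond_tol = 1e12) {
  cl <- match.call()
  src <- .as_source(genotypes, block_size = block_size)

  # --- sample alignment -----------------------------------------------------
  keep_ind <- NULL
  if (is.character(phenotype)) {
    if (is.null(src$fam)) stop("phenotype file input requires PLINK genotypes")
    ph <- read_pheno(phenotype)
    key_fam <- paste(src$fam$fid, src$fam$iid)
    key_ph <- paste(ph$fid, ph$iid)
    hit <- match(key_fam, key_ph)
    y_all <- ph[[3]][hit]
    keep_ind <- which(!is.na(hit) & !is.na(y_all))
    if (!length(keep_ind)) stop("no overlapping samples between FAM and phenotype file")
    if (length(keep_ind) < src$n) {
      message(sprintf("%d of %d FAM samples matched a non-missing phenotype",
                      length(keep_ind), src$n))
    }
    y <- y_all[keep_ind]
  } else {
    y <- as.numeric(phenotype)
    if (length(y) != src$n) stop("phenotype length does not match number of individuals")
    if (anyNA(y)) {
      keep_ind <- which(!is.na(y))
      y <- y[keep_ind]
    }
  }
  if (!is.null(keep_ind)) src <- .subset_source(src, keep_ind)
  n <- src$n

  W <- NULL
  if (!is.null(covariates)) {
    if (is.character(covariates)) {
      cv <- read_pheno(covariates)
      key_fam <- paste(src$fam$fid, src$fam$iid)
      hit <- match(key_fam, paste(cv$fid, cv$iid))
      if (anyNA(hit)) stop("covariate file is missing ", sum(is.na(hit)), " sample(s)")
      W <- as.matrix(cv[hit, -(1:2), drop = FALSE])
    } else {
      W <- as.matrix(covariates)
      if (!is.null(keep_ind)) W <- W[keep_ind, , drop = FALSE]
      if (nrow(W) != n) stop("covariate rows do not match individuals")
    }
  }

  # --- QC and partition -----------------------------------------------------
  stats_qc <- snp_qc(src)
  keep <- if (isTRUE(qc)) {
    qc_keep(stats_qc, max_missing = max_missing, min_maf = min_maf,
            hwe_alpha = hwe_alpha)
  } else {
    !is.na(stats_qc$freq) & stats_qc$freq > 0 & stats_qc$freq < 1
  }
  m_kept <- sum(keep)
  if (m_kept < 2L) stop("fewer than 2 SNPs pass QC")
  freq <- stats_qc$freq

  if (is.null(partition)) {
    need_bins <- length(maf_breaks) > 0L || ld_quantiles > 1L
    sc_kept <- NULL
    if (need_bins && ld_quantiles > 1L) {
      if (!is.null(scores)) {
        if (length(scores) != src$m) stop("scores must cover all input SNPs")
        sc_kept <- scores[keep]
      } else {
        Xfull <- .materialize_std(src, keep, freq)
        sc_kept <- ld_scores(Xfull, bp = stats_qc$bp[keep],
                             chrom = stats_qc$chrom[keep],
                             window_bp = ld_window_bp)
      }
    }
    partition <- maf_ld_partition(freq[keep], scores = sc_kept,
                                  maf_breaks = maf_breaks,
                                  n_score_bins = if (need_bins) ld_quantiles else 1L)
  } else {
    if (partition$M != m_kept) {
      stop("partition covers ", partition$M, " SNPs but ", m_kept, " pass QC")
    }
  }

  # --- moments, solve, jackknife -------------------------------------------
  pc <- project_covariates(y, W)
  Z <- rhe_sketch(n, B = B, seed = seed)
  Z <- project_out(pc$projector, Z)
  stream <- .std_stream(src, keep, freq)
  acc <- rhe_accumulate(stream, partition, Z, pc$y, n_blocks = n_blocks,
                        projector = pc$projector)
  fit <- .rhe_fit_from_acc(acc, cond_tol = cond_tol, nonneg = nonneg)

  structure(c(fit, list(
    partition = partition, n = n, m_input = src$m, M = m_kept,
    n_dropped_snps = src$m - m_kept, B = B, J = acc$J, seed = seed,
    n_eff = acc$n_eff, proj_y = pc$y, qc = stats_qc, keep_snps = keep,
    genotype_ref = if (is.character(genotypes)) genotypes else NULL,
    call = cl)), class = "rhe_mc")
}

# Full + delete-block fits and summaries from a completed accumulator.
.rhe_fit_from_acc <- function(acc, cond_tol = 1e12, nonneg = FALSE) {
  sys <- rhe_system(acc)
  sigma2 <- drop(vc_solve(sys$T_hat, sys$n_eff, sys$c_mat, sys$yty,
                          cond_tol = cond_tol))
  K <- acc$K
  jsys <- rhe_jackknife_systems(acc)
  full <- attr(jsys, "full")
  summ <- vc_summary(sigma2, full$Mk, acc$M, mode = acc$mode,
                     overlap = full$overlap, wsum = full$wsum)
  deletes <- rhe_delete_fits(acc, systems = jsys, cond_tol = cond_tol)
  J <- acc$J
  del_h2 <- numeric(J)
  del_h2c <- matrix(NA_real_, J, K)
  del_enr <- matrix(NA_real_, J, K)
  for (j in seq_len(J)) {
    s <- vc_summary(deletes[j, , 1], jsys[[j]]$Mk, acc$M - sum(acc$counts[, j]),
                    mode = acc$mode, overlap = jsys[[j]]$overlap,
                    wsum = jsys[[j]]$wsum)
    del_h2[j] <- s$h2_total
    del_h2c[j, ] <- s$h2_comp
    del_enr[j, ] <- s$enrichment
  }
  se_sigma2 <- jackknife_se(deletes[, , 1])
  se_h2 <- jackknife_se(matrix(del_h2, ncol = 1))
  se_h2c <- jackknife_se(del_h2c)
  se_enr <- jackknife_se(del_enr)
  zt <- enrichment_test(summ$enrichment, se_enr)
  if (nonneg) sigma2 <- pmax(sigma2, 0)
  list(sigma2 = stats::setNames(sigma2, c(paste0("sigma2_", seq_len(K)), "sigma2_e")),
       se_sigma2 = se_sigma2,
       h2_total = summ$h2_total, se_h2_total = drop(se_h2),
       h2_comp = summ$h2_comp, se_h2_comp = se_h2c,
       enrichment = summ$enrichment, se_enrichment = se_enr,
       z_enrichment = zt$z, p_enrichment = zt$p,
       Mk = full$Mk, T_hat = sys$T_hat, c_vec = drop(sys$c_mat),
       yty = acc$yty, mode = acc$mode,
       delete_block = list(sigma2 = deletes[, , 1], h2_total = del_h2,
                           h2_comp = del_h2c, enrichment = del_enr))
}

.subset_source <- function(src, rows) {
  parent <- src
  next_block <- function() {
    blk <- parent$next_block()
    if (is.null(blk)) return(NULL)
    blk$counts <- blk$counts[rows, , drop = FALSE]
    blk
  }
  structure(list(n = length(rows), m = parent$m, snps = parent$snps,
                 fam = if (!is.null(parent$fam)) parent$fam[rows, , drop = FALSE] else NULL,
                 next_block = next_block, reset = parent$reset,
                 block_size = parent$block_size),
            class = "geno_source")
}

#' @export
print.rhe_mc <- function(x, digits = 4, ...) {
  cat("Randomized multi-component Haseman-Elston regression\n")
  cat(sprintf("  N = %d individuals, M = %d SNPs (%d dropped by QC), K = %d components\n",
              x$n, x$M, x$n_dropped_snps, length(x$Mk)))
  cat(sprintf("  B = %d sketch vectors, J = %d jackknife blocks, seed = %d\n",
              x$B, x$J, as.integer(x$seed)))
  cat(sprintf("  h2_SNP = %s (SE %s)   sigma2_e = %s\n",
              format(x$h2_total, digits = digits),
              format(x$se_h2_total, digits = digits),
              format(unname(x$sigma2["sigma2_e"]), digits = digits)))
  invisible(x)
}

#' Summarize a fitted heritability model
#'
#' @param object An `"rhe_mc"` fit.
#' @param ... Unused.
#' @return An object of class `"summary.rhe_mc"` whose `components` element is
#'   a data.frame with one row per variance component: size `M_k`, variance
#'   component, per-component heritability, enrichment, their jackknife SEs,
#'   and the enrichment Z and p-value.
#' @export
summary.rhe_mc <- function(object, ...) {
  K <- length(object$Mk)
  comp <- data.frame(
    name = names(object$Mk) %||% object$partition$names,
    M = object$Mk,
    sigma2 = object$sigma2[seq_len(K)],
    sigma2_se = object$se_sigma2[seq_len(K)],
    h2 = object$h2_comp,
    h2_se = object$se_h2_comp,
    enrichment = object$enrichment,
    enrichment_se = object$se_enrichment,
    z = object$z_enrichment,
    p = object$p_enrichment,
    row.names = NULL)
  structure(list(components = comp, h2_total = object$h2_total,
                 se_h2_total = object$se_h2_total,
                 sigma2_e = unname(object$sigma2["sigma2_e"]),
                 sigma2_e_se = object$se_sigma2[K + 1L],
                 n = object$n, M = object$M, B = object$B, J = object$J,
                 seed = object$seed),
            class = "summary.rhe_mc")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.summary.rhe_mc <- function(x, digits = 4, ...) {
  cat(sprintf("h2_SNP = %s (SE %s), sigma2_e = %s (SE %s)\n",
              format(x$h2_total, digits = digits),
              format(x$se_h2_total, digits = digits),
              format(x$sigma2_e, digits = digits),
              format(x$sigma2_e_se, digits = digits)))
  cat(sprintf("N = %d, M = %d, B = %d, J = %d, seed = %d\n\n",
              x$n, x$M, x$B, x$J, as.integer(x$seed)))
  print(format(x$components, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.rhe_mc <- function(object, ...) object$sigma2

#' @export
residuals.rhe_mc <- function(object, ...) object$proj_y

#' @export
plot.rhe_mc <- function(x, ...) {
  K <- length(x$Mk)
  mid <- graphics::barplot(x$enrichment, names.arg = x$partition$names,
                           las = 2, ylab = "heritability enrichment",
                           ylim = range(0, x$enrichment + 2 * x$se_enrichment,
                                        x$enrichment - 2 * x$se_enrichment,
                                        1.2, na.rm = TRUE), ...)
  graphics::arrows(mid, x$enrichment - 2 * x$se_enrichment,
                   mid, x$enrichment + 2 * x$se_enrichment,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Simulate phenotypes from a fitted variance-component model
#'
#' Draws `beta_k ~ N(0, max(sigma^2_k, 0) / M_k)` per component and
#' `y = sum_k X_k beta_k + eps` with `eps ~ N(0, max(sigma^2_e, 0))`,
#' streaming the genotypes the fit was produced from. Negative fitted
#' components contribute nothing (with a warning).
#'
#' @param object An `"rhe_mc"` fit.
#' @param nsim Number of phenotype replicates.
#' @param seed Optional seed.
#' @param genotypes Genotype input; defaults to the PLINK prefix recorded in
#'   the fit (matrix inputs are not retained, so pass them again).
#' @param ... Unused.
#' @return N x nsim data.frame of simulated phenotypes.
#' @export
simulate.rhe_mc <- function(object, nsim = 1, seed = NULL, genotypes = NULL, ...) {
  if (!is.null(seed)) {
    old_rng <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    } else NULL
    on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng, globalenv()))
    set.seed(as.integer(seed))
  }
  genotypes <- genotypes %||% object$genotype_ref
  if (is.null(genotypes)) stop("pass `genotypes` (they are not stored in the fit)")
  src <- .as_source(genotypes)
  if (src$n != object$n) stop("genotypes do not match the fitted sample")
  K <- length(object$Mk)
  s2 <- object$sigma2
  if (any(s2 < 0)) warning("negative fitted variance components truncated at 0 for simulation")
  s2 <- pmax(s2, 0)
  stream <- .std_stream(src, object$keep_snps, object$qc$freq)
  assign_k <- object$partition$assign
  per_snp_sd <- if (!is.null(assign_k)) {
    sqrt(s2[assign_k] / object$Mk[assign_k])
  } else {
    v <- numeric(object$M)
    for (k in seq_len(K)) {
      v[object$partition$members[[k]]] <- v[object$partition$members[[k]]] +
        s2[k] / object$Mk[k] * object$partition$weights[[k]]
    }
    sqrt(v)
  }
  Y <- matrix(stats::rnorm(object$n * nsim, sd = sqrt(s2[K + 1L])), object$n, nsim)
  repeat {
    blk <- stream$next_block()
    if (is.null(blk)) break
    Bm <- matrix(stats::rnorm(length(blk$idx) * nsim), length(blk$idx), nsim) *
      per_snp_sd[blk$idx]
    Y <- Y + blk$X %*% Bm
  }
  as.data.frame(Y)
}
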