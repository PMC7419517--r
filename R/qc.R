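#' Per-SNP quality-control statistics
#'
#' Computes, in one pass over a genotype source, the counted-allele frequency
#' (over non-missing calls only), the missingness rate and the 1-df chi-square
#' Hardy-Weinberg goodness-of-fit p-value for every SNP.
#'
#' @param genotypes Counts matrix, PLINK prefix, or genotype source.
#' @return data.frame with columns id, chrom, bp, freq, maf, missing, hwe_p.
#' @export
snp_qc <- function(genotypes) {
  src <- .as_source(genotypes)
  src$reset()
  freq <- miss <- hwe <- numeric(src$m)
  repeat {
    blk <- src$next_block()
    if (is.null(blk)) break
    x <- blk$counts
    n <- nrow(x)
    nm <- colSums(!is.na(x))
    s <- colSums(x, na.rm = TRUE)
    f <- ifelse(nm > 0, s / (2 * nm), NA_real_)
    n2 <- colSums(x == 2L, na.rm = TRUE)
    n1 <- colSums(x == 1L, na.rm = TRUE)
    n0 <- nm - n1 - n2
    hp <- .hwe_chisq_p(n2, n1, n0)
    freq[blk$idx] <- f
    miss[blk$idx] <- 1 - nm / n
    hwe[blk$idx] <- hp
  }
  data.frame(id = src$snps$id, chrom = src$snps$chrom, bp = src$snps$bp,
             freq = freq, maf = pmin(freq, 1 - freq), missing = miss,
             hwe_p = hwe, stringsAsFactors = FALSE)
}

# 1-df chi-square HWE goodness of fit on genotype counts (hom counted-allele,
# het, hom other) against expectations from the observed allele frequency.
.hwe_chisq_p <- function(n2, n1, n0) {
  n <- n2 + n1 + n0
  f <- ifelse(n > 0, (2 * n2 + n1) / (2 * n), NA_real_)
  e2 <- n * f^2
  e1 <- n * 2 * f * (1 - f)
  e0 <- n * (1 - f)^2
  stat <- ifelse(f > 0 & f < 1,
                 (n2 - e2)^2 / e2 + (n1 - e1)^2 / e1 + (n0 - e0)^2 / e0,
                 NA_real_)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' SNP keep-mask from QC thresholds
#'
#' SNPs are removed when missingness exceeds `max_missing`, minor allele
#' frequency falls below `min_maf`, or the Hardy-Weinberg chi-square test
#' p-value falls below `hwe_alpha`. Monomorphic SNPs are always removed.
#' Defaults match common array QC: 1\% missingness, 1\% MAF, HWE 1e-7.
#'
#' @param stats data.frame from [snp_qc()].
#' @param max_missing,min_maf,hwe_alpha Thresholds.
#' @return Logical keep-mask over SNPs.
#' @export
qc_keep <- function(stats, max_missing = 0.01, min_maf = 0.01, hwe_alpha = 1e-7) {
  poly <- !is.na(stats$freq) & stats$freq > 0 & stats$freq < 1
  keep <- poly &
    stats$missing <= max_missing &
    stats$maf >= min_maf &
    (!is.na(stats$hwe_p) & stats$hwe_p >= hwe_alpha)
  keep
}

#' Standardize a genotype block
#'
#' Missing calls are mean-imputed (2 * freq), each column is centered, then
#' rescaled so its sum of squares equals N exactly, matching the model
#' constraint sum(x) = 0, sum(x^2) = N for every SNP. The rescaling uses the
#' empirical post-imputation column variance, so that the constraint holds
#' regardless of departures from binomial sampling.
#'
#' @param counts Individuals x SNPs block of dosages (0/1/2/NA).
#' @param freq In-sample counted-allele frequencies of the block's SNPs,
#'   strictly inside (0, 1); used only for mean imputation.
#' @return Numeric matrix of the same shape, each column with sum 0 and sum of
#'   squares N.
#' @export
standardize_genotypes <- function(counts, freq) {
  n <- nrow(counts)
  if (length(freq) != ncol(counts)) stop("freq length must match SNP count")
  if (any(!is.finite(freq)) || any(freq <= 0) || any(freq >= 1)) {
    stop("degenerate SNP: frequency must lie strictly in (0, 1); run QC first")
  }
  x <- counts
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    na <- which(is.na(x))
    x[na] <- (2 * freq)[(na - 1L) %/% n + 1L]
  }
  x <- sweep(x, 2L, colMeans(x), `-`)
  ss <- colSums(x^2)
  if (any(ss == 0)) stop("degenerate SNP: constant column after imputation")
  sweep(x, 2L, sqrt(ss / n), `/`)
}

# Stream standardized blocks of the QC-kept SNPs of a source.
# `keep` and `freq` are over the source's full SNP set; emitted `idx` are
# positions in the kept-SNP ordering (1..M_kept).
.std_stream <- function(src, keep, freq) {
  src$reset()
  kept_rank <- cumsum(keep)
  next_block <- function() {
    repeat {
      blk <- src$next_block()
      if (is.null(blk)) return(NULL)
      sel <- keep[blk$idx]
      if (!any(sel)) next
      gi <- blk$idx[sel]
      X <- standardize_genotypes(blk$counts[, sel, drop = FALSE], freq[gi])
      return(list(X = X, idx = kept_rank[gi]))
    }
  }
  list(n = src$n, m = sum(keep), next_block = next_block,
       reset = function() src$reset())
}

# Materialize the standardized kept-SNP matrix (needed for in-sample LD
# scores and the dense oracle).
.materialize_std <- function(src, keep, freq, max_entries = 2.5e8) {
  mkept <- sum(keep)
  if (as.double(src$n) * mkept > max_entries) {
    stop("standardized genotype matrix too large to materialize; ",
         "supply a per-SNP score file instead of in-sample LD scores")
  }
  out <- matrix(0, src$n, mkept)
  st <- .std_stream(src, keep, freq)
  repeat {
    blk <- st$next_block()
    if (is.null(blk)) break
    out[, blk$idx] <- blk$X
  }
  out
}
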