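#' Simulate genotype matrices
#'
#' Independent mode draws allele counts Binomial(2, f_m) i.i.d. across
#' individuals and SNPs. Blockwise-LD mode generates, per haplotype, a latent
#' Gaussian AR(rho) process along SNPs within blocks and thresholds it at
#' `qnorm(f_m)`, which preserves the marginal frequencies while inducing
#' positive LD within blocks. Positions are spaced 1 kb apart on one
#' chromosome.
#'
#' @param n Individuals.
#' @param m SNPs.
#' @param maf Either a length-2 range for Uniform sampling of frequencies
#'   (default `c(0.01, 0.5)`) or a function `function(m)` returning m
#'   frequencies in (0, 1).
#' @param ld NULL for independent SNPs, or `list(rho = , block_len = )` for
#'   blockwise AR LD.
#' @param seed Optional integer seed.
#' @return List with `counts` (n x m integer matrix), `freq` (the target
#'   frequencies), `snps` (BIM-style metadata).
#' @export
sim_genotypes <- function(n, m, maf = c(0.01, 0.5), ld = NULL, seed = NULL) {
  if (!is.null(seed)) {
    old_rng <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    } else NULL
    on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng, globalenv()))
    set.seed(as.integer(seed))
  }
  f <- if (is.function(maf)) maf(m) else stats::runif(m, maf[1], maf[2])
  stopifnot(all(f > 0 & f < 1))
  if (is.null(ld) || (!is.null(ld$rho) && ld$rho == 0)) {
    counts <- matrix(stats::rbinom(n * m, 2L, rep(f, each = n)), n, m)
  } else {
    rho <- ld$rho
    blen <- if (is.null(ld$block_len)) 50L else as.integer(ld$block_len)
    thr <- stats::qnorm(f)
    counts <- matrix(0L, n, m)
    for (h in 1:2) {
      L <- matrix(stats::rnorm(n * m), n, m)
      sc <- sqrt(1 - rho^2)
      for (j in seq_len(m)[-1]) {
        if ((j - 1L) %% blen != 0L) L[, j] <- rho * L[, j - 1L] + sc * L[, j]
      }
      counts <- counts + (L < rep(thr, each = n))
    }
  }
  snps <- data.frame(chrom = "1", id = paste0("snp", seq_len(m)), cm = 0,
                     bp = 1000L * seq_len(m), a1 = "A", a2 = "C",
                     stringsAsFactors = FALSE)
  list(counts = counts, freq = f, snps = snps)
}

#' Select causal variants
#'
#' Samples `round(p * M)` causal SNPs uniformly among the SNPs whose MAF lies
#' in `window`.
#'
#' @param freq Allele frequencies (MAF taken as `pmin(f, 1 - f)`).
#' @param p Causal fraction of the full SNP panel, in (0, 1].
#' @param window MAF window `c(lo, hi)` for eligible SNPs.
#' @param seed Optional seed.
#' @return Logical causal mask of length M.
#' @export
sim_causal <- function(freq, p = 1, window = c(0, 0.5), seed = NULL) {
  if (!is.null(seed)) {
    old_rng <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    } else NULL
    on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng, globalenv()))
    set.seed(as.integer(seed))
  }
  stopifnot(p > 0, p <= 1)
  maf <- pmin(freq, 1 - freq)
  eligible <- which(maf >= window[1] & maf <= window[2])
  ncausal <- max(1L, round(p * length(freq)))
  if (length(eligible) == 0L) stop("no SNPs in the causal MAF window")
  if (length(eligible) < ncausal) {
    stop("causal MAF window holds ", length(eligible),
         " SNPs but ", ncausal, " causal variants requested")
  }
  mask <- logical(length(freq))
  mask[if (length(eligible) == ncausal) eligible else sample(eligible, ncausal)] <- TRUE
  mask
}

#' Simulate phenotypes under a MAF/LD-coupled architecture
#'
#' Per-SNP effect-size variances follow
#' `sigma^2_m = S * c_m * w_m^b * [f_m (1 - f_m)]^a`, with `S` normalizing
#' the causal variances to sum to `h2`; effects act on standardized
#' genotypes, `beta_m ~ N(0, sigma^2_m)`, and
#' `y = X beta + eps`, `eps ~ N(0, (1 - h2) I)`. `a = b = 0` is the
#' GCTA-style architecture (equal expected heritability per standardized
#' SNP); `a = 0.75, b = 1` with LD-derived weights is the LDAK-style one.
#'
#' @param X Standardized genotype matrix (individuals x SNPs).
#' @param freq Per-SNP allele frequencies.
#' @param h2 True SNP heritability in [0, 1].
#' @param causal Logical causal mask (default: all SNPs causal).
#' @param a MAF-coupling exponent (0 or 0.75 in common use).
#' @param b Weight-coupling exponent (0 or 1 in common use).
#' @param weights Non-negative per-SNP scores `w_m` (e.g. LDAK weights);
#'   default 1, in which case `b` has no effect.
#' @param reps Number of independent phenotype replicates to draw.
#' @param seed Optional seed.
#' @return List with `y` (N-vector if `reps = 1`, else N x reps matrix) and
#'   `truth`: per-SNP variances `sigma2_m`, the causal mask, and
#'   `h2_by` -- a function mapping an [annotation_set()] to true
#'   per-component heritabilities.
#' @export
sim_phenotype <- function(X, freq, h2, causal = NULL, a = 0, b = 0,
                          weights = NULL, reps = 1L, seed = NULL) {
  if (!is.null(seed)) {
    old_rng <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    } else NULL
    on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng, globalenv()))
    set.seed(as.integer(seed))
  }
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  n <- nrow(X)
  m <- ncol(X)
  if (length(freq) != m) stop("freq length must match ncol(X)")
  if (is.null(causal)) causal <- rep(TRUE, m)
  if (is.null(weights)) weights <- rep(1, m)
  if (any(weights < 0)) stop("weights must be non-negative")
  raw <- as.numeric(causal) * weights^b * (freq * (1 - freq))^a
  sigma2_m <- if (h2 > 0) raw * (h2 / sum(raw)) else numeric(m)
  cset <- which(causal)
  Y <- matrix(stats::rnorm(n * reps, sd = sqrt(1 - h2)), n, reps)
  if (h2 > 0 && length(cset)) {
    Bm <- matrix(stats::rnorm(length(cset) * reps), length(cset), reps) *
      sqrt(sigma2_m[cset])
    Y <- Y + X[, cset, drop = FALSE] %*% Bm
  }
  truth <- list(
    sigma2_m = sigma2_m, causal = causal, h2 = h2, a = a, b = b,
    h2_by = function(annot) {
      vapply(annot$members, function(s) sum(sigma2_m[s]), numeric(1))
    })
  list(y = if (reps == 1L) drop(Y) else Y, truth = truth)
}

#' Write a simulated dataset as a PLINK fixture
#'
#' Emits `prefix.bed/.bim/.fam`, a whitespace phenotype file
#' (`prefix.pheno`), and a per-SNP truth table (`prefix.truth.tsv`).
#'
#' @param sim Output of [sim_genotypes()].
#' @param y Phenotype vector (or matrix; first column is written).
#' @param prefix Output path prefix.
#' @param truth Optional truth list from [sim_phenotype()].
#' @return The prefix, invisibly.
#' @export
write_fixture <- function(sim, y, prefix, truth = NULL) {
  n <- nrow(sim$counts)
  fam <- data.frame(fid = paste0("F", seq_len(n)), iid = paste0("I", seq_len(n)),
                    pat = "0", mat = "0", sex = "0", pheno = "-9",
                    stringsAsFactors = FALSE)
  write_plink(sim$counts, prefix, snps = sim$snps, fam = fam)
  yv <- if (is.matrix(y)) y[, 1] else y
  utils::write.table(data.frame(fam$fid, fam$iid, yv),
                     paste0(prefix, ".pheno"), quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(truth)) {
    utils::write.table(
      data.frame(id = sim$snps$id, sigma2 = truth$sigma2_m,
                 causal = as.integer(truth$causal)),
      paste0(prefix, ".truth.tsv"), quote = FALSE, sep = "\t", row.names = FALSE)
  }
  invisible(prefix)
}

#' One-call simulated dataset
#'
#' Convenience wrapper chaining [sim_genotypes()], [sim_causal()] and
#' [sim_phenotype()] with independent sub-seed streams derived from one
#' master seed (genotypes / causal mask / effects-and-noise).
#'
#' @inheritParams sim_genotypes
#' @inheritParams sim_phenotype
#' @param causal_frac Causal fraction p.
#' @param causal_window MAF window for causal variants.
#' @param seed Master seed.
#' @return List with `counts`, `freq`, `snps`, `X` (standardized), `y`,
#'   `truth`.
#' @export
sim_dataset <- function(n, m, h2 = 0.5, causal_frac = 1,
                        causal_window = c(0, 0.5), a = 0, b = 0,
                        weights = NULL, maf = c(0.01, 0.5), ld = NULL,
                        reps = 1L, seed = 1L) {
  ss <- seed_streams(seed, 3L)
  g <- sim_genotypes(n, m, maf = maf, ld = ld, seed = ss[1])
  obs_f <- colMeans(g$counts) / 2
  X <- standardize_genotypes(g$counts, obs_f)
  mask <- sim_causal(obs_f, p = causal_frac, window = causal_window, seed = ss[2])
  ph <- sim_phenotype(X, obs_f, h2 = h2, causal = mask, a = a, b = b,
                      weights = weights, reps = reps, seed = ss[3])
  list(counts = g$counts, freq = obs_f, snps = g$snps, X = X,
       y = ph$y, truth = ph$truth)
}
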