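#' Gaussian random sketch
#'
#' Draws the `B` standard-normal probe vectors of the Hutchinson trace
#' estimator: `E[z' C z] = tr(C)` for any z with zero mean and identity
#' covariance. A single sketch is shared across all components and jackknife
#' blocks, which is what makes the cross-component trace estimates and the
#' delete-block reassembly consistent.
#'
#' @param n Number of individuals.
#' @param B Number of random vectors (default 10).
#' @param seed Optional integer seed for reproducibility.
#' @return n x B matrix of i.i.d. standard normals.
#' @export
rhe_sketch <- function(n, B = 10L, seed = NULL) {
  stopifnot(n >= 1, B >= 1)
  .with_seed(seed, matrix(stats::rnorm(as.double(n) * B), n, B))
}

#' Single-pass accumulation of randomized method-of-moments statistics
#'
#' Streams the standardized genotypes once. For every genotype block it
#' computes `X_block' z_b` and `X_block' y`, scatters the contributions into
#' the owning component(s) (applying `sqrt(a_k)` weights in continuous mode),
#' and accumulates the sketch images `X_k X_k' z_b` and the quadratic-form
#' partials `||X_k' y||^2` separately for each of `n_blocks` contiguous
#' jackknife SNP blocks. Everything the normal equations and the delete-block
#' jackknife need is retained; the genotypes are never revisited.
#'
#' @param genotypes Standardized matrix (individuals x SNPs, e.g. from
#'   [standardize_genotypes()]) or a standardized block stream.
#' @param annot An [annotation_set()] over the same SNPs.
#' @param sketch n x B matrix from [rhe_sketch()].
#' @param y Phenotype vector, or an n x R matrix to accumulate R phenotypes
#'   against the shared sketch in one pass. Must already be centered (and
#'   covariate-projected where applicable; see [project_covariates()]).
#' @param n_blocks Number of jackknife blocks J (>= 2), contiguous in genome
#'   order.
#' @param projector Optional projector (from [project_covariates()]) applied
#'   to the sketch images so that all moments refer to covariate-projected
#'   data. The sketch and `y` must already be projected by the caller.
#' @param block_size SNPs per streaming block when `genotypes` is a matrix.
#' @return An object of class `"rhe_acc"`.
#' @export
rhe_accumulate <- function(genotypes, annot, sketch, y, n_blocks = 100L,
                           projector = NULL, block_size = 1000L) {
  if (is.matrix(genotypes)) {
    Xmat <- genotypes
    stream <- local({
      pos <- 0L
      list(n = nrow(Xmat), m = ncol(Xmat),
           next_block = function() {
             if (pos >= ncol(Xmat)) return(NULL)
             k <- min(block_size, ncol(Xmat) - pos)
             idx <- pos + seq_len(k)
             pos <<- pos + k
             list(X = Xmat[, idx, drop = FALSE], idx = idx)
           },
           reset = function() pos <<- 0L)
    })
  } else {
    stream <- genotypes
  }
  n <- stream$n
  M <- stream$m
  if (annot$M != M) stop("annotation set covers ", annot$M, " SNPs but genotypes have ", M)
  J <- as.integer(n_blocks)
  if (J < 2L) stop("need at least 2 jackknife blocks")
  if (J > M) stop("more jackknife blocks than SNPs")
  Y <- if (is.matrix(y)) y else matrix(y, ncol = 1L)
  if (nrow(Y) != n) stop("phenotype length does not match individuals")
  R <- ncol(Y)
  B <- ncol(sketch)
  K <- annot$K
  if (nrow(sketch) != n) stop("sketch rows must equal individuals")

  jb <- ceiling(seq_len(M) * J / M)          # jackknife block of each SNP
  ent <- .annot_entries(annot)
  ent_jb <- jb[ent$snp]

  # per-(component, jackknife block) SNP counts and weight sums; overlap
  # counts feed the overlapping-annotation heritability decomposition
  counts <- matrix(0L, K, J)
  wsum <- matrix(0, K, J)
  cj <- ent$comp + K * (ent_jb - 1L)
  counts[] <- tabulate(cj, nbins = K * J)
  ws <- rowsum(ent$w, cj)
  wsum[as.integer(rownames(ws))] <- ws[, 1]
  overlap <- NULL
  if (annot$mode == "overlapping") {
    overlap <- array(0, c(K, K, J))
    memb <- matrix(FALSE, M, K)
    for (k in seq_len(K)) memb[annot$members[[k]], k] <- TRUE
    for (j in seq_len(J)) {
      mj <- memb[jb == j, , drop = FALSE]
      overlap[, , j] <- crossprod(mj)
    }
  }

  images <- lapply(seq_len(J), function(j) matrix(0, n, K * B))
  quad <- array(0, c(K, J, R))
  stream$reset()
  repeat {
    blk <- stream$next_block()
    if (is.null(blk)) break
    Xb <- blk$X
    idx <- blk$idx
    U <- crossprod(Xb, sketch)   # m_b x B
    W <- crossprod(Xb, Y)        # m_b x R
    lo <- findInterval(idx[1] - 0.5, ent$snp) + 1L
    hi <- findInterval(idx[length(idx)] + 0.5, ent$snp)
    if (hi < lo) next
    sub <- lo:hi
    loc <- match(ent$snp[sub], idx)
    grp <- split(seq_along(sub), list(comp = ent$comp[sub], j = ent_jb[sub]),
                 drop = TRUE)
    for (gname in names(grp)) {
      gi <- grp[[gname]]
      k <- ent$comp[sub[gi[1]]]
      j <- ent_jb[sub[gi[1]]]
      cols <- loc[gi]
      w <- ent$w[sub[gi]]
      aw <- if (all(w == 1)) U[cols, , drop = FALSE] else w * U[cols, , drop = FALSE]
      img <- Xb[, cols, drop = FALSE] %*% aw
      tgt <- (seq_len(B) - 1L) * K + k
      images[[j]][, tgt] <- images[[j]][, tgt] + img
      wq <- if (all(w == 1)) W[cols, , drop = FALSE]^2 else w * W[cols, , drop = FALSE]^2
      quad[k, j, ] <- quad[k, j, ] + colSums(wq)
    }
  }
  if (!is.null(projector)) {
    for (j in seq_len(J)) images[[j]] <- project_out(projector, images[[j]])
  }
  if (any(rowSums(counts) == 0L)) {
    stop("component with zero SNPs after streaming")
  }
  structure(list(images = images, quad = quad, counts = counts, wsum = wsum,
                 overlap = overlap, yty = colSums(Y^2), n = n, M = M,
                 n_eff = n - if (is.null(projector)) 0L else projector$rank,
                 K = K, B = B, J = J, R = R, mode = annot$mode,
                 sizes = annot$sizes),
            class = "rhe_acc")
}

#' @export
print.rhe_acc <- function(x, ...) {
  cat(sprintf(
    "rhe_acc: N=%d, M=%d, K=%d components, B=%d sketch vectors, J=%d jackknife blocks, %d phenotype(s)\n",
    x$n, x$M, x$K, x$B, x$J, x$R))
  invisible(x)
}

# Collapse a (K*B) x (K*B) Gram matrix of sketch images into the K x K
# randomized trace matrix: T[k,l] = sum_b <v_kb, v_lb> / (B * M_k * M_l).
.gram_to_T <- function(G, K, B, Mk) {
  Tsum <- matrix(0, K, K)
  for (b in seq_len(B)) {
    ii <- (b - 1L) * K + seq_len(K)
    Tsum <- Tsum + G[ii, ii]
  }
  Tsum / (B * tcrossprod(Mk))
}

#' Assemble the method-of-moments normal equations
#'
#' Collapses the accumulated sketch images into the randomized trace matrix
#' `T[k,l] ~ tr(K_k K_l)` (Hutchinson average over the B probes, scaled by
#' `1/(M_k M_l)`), and the quadratic forms `c_k = y' K_k y`. The trace of each
#' GRM is `n_eff` exactly because the genotype columns are standardized.
#'
#' @param acc An accumulator from [rhe_accumulate()].
#' @return List with `T_hat` (K x K), `b_vec` (all `n_eff`), `c_mat`
#'   (K x R), `yty` (length R), `n_eff`, `Mk`, `M`.
#' @export
rhe_system <- function(acc) {
  V <- Reduce(`+`, acc$images)
  G <- crossprod(V)
  Mk <- rowSums(acc$counts)
  T_hat <- .gram_to_T(G, acc$K, acc$B, Mk)
  qk <- apply(acc$quad, c(1, 3), sum)        # K x R raw ||X_k' y||^2
  c_mat <- qk / Mk
  list(T_hat = T_hat, b_vec = rep(acc$n_eff, acc$K), c_mat = c_mat,
       yty = acc$yty, n_eff = acc$n_eff, Mk = Mk, M = acc$M)
}

#' Solve the bordered normal equations for the variance components
#'
#' Solves `[[T, b], [b', n_eff]] sigma = [c; y'y]` by a direct dense solve;
#' when the system's condition number exceeds `cond_tol` (or it is exactly
#' singular, e.g. duplicated components) a minimum-norm least-squares solution
#' is returned with a warning. Estimates are not constrained to be
#' non-negative.
#'
#' @param T_hat K x K trace matrix.
#' @param n_eff Effective sample size (enters the `b` vector and corner).
#' @param c_mat K-vector or K x R matrix of quadratic forms.
#' @param yty Phenotype sum(s) of squares, length R.
#' @param cond_tol Condition-number cutoff for the least-squares fallback.
#' @return (K+1) x R matrix: rows are `sigma^2_1 ... sigma^2_K, sigma^2_e`.
#' @export
vc_solve <- function(T_hat, n_eff, c_mat, yty, cond_tol = 1e12) {
  K <- nrow(T_hat)
  cm <- if (is.matrix(c_mat)) c_mat else matrix(c_mat, ncol = 1L)
  A <- rbind(cbind(T_hat, n_eff), c(rep(n_eff, K), n_eff))
  rhs <- rbind(cm, yty)
  dimnames(A) <- NULL
  kap <- tryCatch(kappa(A, exact = FALSE), error = function(e) Inf)
  if (is.finite(kap) && kap <= cond_tol) {
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (!is.null(sol)) {
      dimnames(sol) <- NULL
      return(sol)
    }
  }
  warning("ill-conditioned normal equations; using minimum-norm least squares")
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * 1e-12
  sol <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos])
  sol
}

#' Heritability and enrichment summaries from solved variance components
#'
#' Total SNP heritability is `sum(sigma^2_k) / (sum(sigma^2_k) + sigma^2_e)`.
#' Per-component heritability depends on the annotation mode: in disjoint mode
#' it is `sigma^2_k / denom`; with overlapping binary annotations the
#' per-SNP variances `sigma^2_j / M_j` of every annotation containing a SNP
#' are summed over the SNPs of annotation k; with continuous annotations the
#' numerator is `(sigma^2_k / M_k) * sum_i a[k, i]` and the denominator uses
#' the same weighted genetic variance. Enrichment is the per-SNP heritability
#' share relative to the SNP share, `(h2_k / h2) / (M_k / M)`, with null
#' value 1; it is NA when total heritability is zero.
#'
#' @param sigma2 (K+1)-vector `(sigma^2_1..K, sigma^2_e)`.
#' @param Mk Component sizes.
#' @param M Total SNPs.
#' @param mode Annotation mode.
#' @param overlap K x K matrix of pairwise annotation overlap counts
#'   (overlapping mode).
#' @param wsum Per-component annotation weight sums (continuous mode).
#' @return List with `h2_total`, `h2_comp`, `enrichment`.
#' @export
vc_summary <- function(sigma2, Mk, M, mode = "disjoint", overlap = NULL,
                       wsum = NULL) {
  K <- length(Mk)
  s2g <- sigma2[seq_len(K)]
  s2e <- sigma2[K + 1L]
  if (mode == "continuous") {
    if (is.null(wsum)) stop("wsum required in continuous mode")
    gvar <- (s2g / Mk) * wsum
    denom <- sum(gvar) + s2e
    h2c <- gvar / denom
  } else if (mode == "overlapping") {
    if (is.null(overlap)) stop("overlap counts required in overlapping mode")
    denom <- sum(s2g) + s2e
    h2c <- as.vector(overlap %*% (s2g / Mk)) / denom
  } else {
    denom <- sum(s2g) + s2e
    h2c <- s2g / denom
  }
  h2 <- if (mode == "continuous") sum((s2g / Mk) * wsum) / denom else sum(s2g) / denom
  enr <- if (h2 != 0) (h2c / h2) / (Mk / M) else rep(NA_real_, K)
  list(h2_total = h2, h2_comp = h2c, enrichment = enr)
}

#' Project covariates out of a phenotype
#'
#' Builds the orthogonal projector off the column span of `[1, W]` and applies
#' it to `y`. The same projector must be applied to the sketch vectors and
#' (via `rhe_accumulate(projector = )`) to the genotype-block images, so that
#' every moment refers to covariate-adjusted data; the effective sample size
#' `n_eff = N - rank` then replaces N in the normal equations.
#'
#' @param y Phenotype vector or matrix.
#' @param W Covariate matrix (N x C), without intercept (one is added), or
#'   NULL for intercept-only centering.
#' @return List with `y` (residualized), `projector` (pass to
#'   [rhe_accumulate()] and use via [project_out()]), `n_eff`, `rank`.
#' @export
project_covariates <- function(y, W = NULL) {
  Y <- if (is.matrix(y)) y else matrix(y, ncol = 1L)
  n <- nrow(Y)
  Wfull <- cbind(intercept = rep(1, n), W)
  qrW <- qr(Wfull)
  if (qrW$rank < ncol(Wfull)) {
    warning("rank-deficient covariates: ", ncol(Wfull) - qrW$rank,
            " dependent column(s) dropped")
  }
  proj <- structure(list(qr = qrW, rank = qrW$rank), class = "rhe_projector")
  res <- project_out(proj, Y)
  list(y = if (is.matrix(y)) res else drop(res), projector = proj,
       n_eff = n - qrW$rank, rank = qrW$rank)
}

#' @rdname project_covariates
#' @param projector A projector from [project_covariates()].
#' @param x Vector or matrix to residualize.
#' @export
project_out <- function(projector, x) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  r <- qr.resid(projector$qr, X)
  if (is.matrix(x)) r else drop(r)
}
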