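#' Delete-one-block jackknife systems
#'
#' Reassembles, for each jackknife block j, the normal-equation ingredients
#' with block j's SNPs removed, purely from the retained per-block partials:
#' `v_kb^(-j) = v_kb - s_kbj`, quadratic forms and component sizes likewise.
#' The genotypes are not re-read and the same random sketch is reused (a fresh
#' sketch per block would add spurious jackknife variance).
#'
#' @param acc Accumulator from [rhe_accumulate()].
#' @return List of per-block systems, each with `T_hat`, `Mk`, `wsum`,
#'   `overlap`, `dropped` (components emptied by the deletion), plus the
#'   full-data system as attribute `"full"`.
#' @export
rhe_jackknife_systems <- function(acc) {
  K <- acc$K; B <- acc$B; J <- acc$J
  V <- Reduce(`+`, acc$images)
  G <- crossprod(V)
  Mk_full <- rowSums(acc$counts)
  systems <- vector("list", J)
  for (j in seq_len(J)) {
    Sj <- acc$images[[j]]
    Cj <- crossprod(V, Sj)
    Qj <- crossprod(Sj)
    Gj <- G - Cj - t(Cj) + Qj
    Mkj <- Mk_full - acc$counts[, j]
    dropped <- which(Mkj == 0L)
    Tj <- .gram_to_T(Gj, K, B, pmax(Mkj, 1L))
    ov <- if (!is.null(acc$overlap)) {
      apply(acc$overlap, c(1, 2), sum) - acc$overlap[, , j]
    } else NULL
    systems[[j]] <- list(T_hat = Tj, Mk = Mkj, wsum = rowSums(acc$wsum) - acc$wsum[, j],
                         overlap = ov, dropped = dropped)
  }
  full <- list(T_hat = .gram_to_T(G, K, B, Mk_full), Mk = Mk_full,
               wsum = rowSums(acc$wsum),
               overlap = if (!is.null(acc$overlap)) apply(acc$overlap, c(1, 2), sum) else NULL)
  attr(systems, "full") <- full
  systems
}

#' Delete-one-block variance-component fits
#'
#' Re-solves the normal equations once per jackknife block (and phenotype)
#' with that block's SNPs removed. Components emptied by a deletion are
#' dropped from that block's system and reported as NA.
#'
#' @param acc Accumulator from [rhe_accumulate()].
#' @param systems Optional precomputed [rhe_jackknife_systems()] (they depend
#'   only on the genotypes and the sketch, so they can be reused across
#'   phenotypes).
#' @param cond_tol Passed to [vc_solve()].
#' @return Array J x (K+1) x R of delete-block `sigma^2` estimates.
#' @export
rhe_delete_fits <- function(acc, systems = NULL, cond_tol = 1e12) {
  if (is.null(systems)) systems <- rhe_jackknife_systems(acc)
  K <- acc$K; J <- acc$J; R <- acc$R
  qk <- apply(acc$quad, c(1, 3), sum)        # K x R raw quadratic forms
  out <- array(NA_real_, c(J, K + 1L, R))
  for (j in seq_len(J)) {
    sys <- systems[[j]]
    qj <- qk - matrix(acc$quad[, j, ], K, R)
    keep <- setdiff(seq_len(K), sys$dropped)
    cj <- qj[keep, , drop = FALSE] / sys$Mk[keep]
    sol <- vc_solve(sys$T_hat[keep, keep, drop = FALSE], acc$n_eff, cj,
                    acc$yty, cond_tol = cond_tol)
    out[j, c(keep, K + 1L), ] <- sol
  }
  out
}

#' Block-jackknife standard errors
#'
#' `se^2 = ((J - 1) / J) * sum_j (theta_(-j) - mean_j theta_(-j))^2`,
#' applied elementwise.
#'
#' @param delete_block J x p matrix of delete-one-block estimates (NAs from
#'   dropped components are ignored).
#' @return Length-p vector of standard errors.
#' @export
jackknife_se <- function(delete_block) {
  X <- as.matrix(delete_block)
  J <- nrow(X)
  if (J < 2L) stop("need at least 2 jackknife blocks")
  ctr <- sweep(X, 2L, colMeans(X, na.rm = TRUE))
  nj <- colSums(!is.na(ctr))
  sqrt((nj - 1) / nj * colSums(ctr^2, na.rm = TRUE))
}

#' Enrichment Z-test
#'
#' Tests the null hypothesis of no enrichment (`e_k = 1`):
#' `Z = (e_k - 1) / se_k` with a two-sided standard-normal p-value.
#'
#' @param enrichment Estimated enrichment(s).
#' @param se Jackknife standard error(s); Z is NA where `se` is 0 or NA.
#' @return List with `z` and `p`.
#' @export
enrichment_test <- function(enrichment, se) {
  z <- ifelse(is.na(se) | se == 0, NA_real_, (enrichment - 1) / se)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
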