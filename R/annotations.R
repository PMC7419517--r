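#' Construct a SNP-to-variance-component map
#'
#' An annotation set assigns each of `M` SNPs to one or more of `K` variance
#' components. Three modes are supported: `disjoint` (every SNP in exactly one
#' component, e.g. MAF/LD bins), `overlapping` (binary annotations that may
#' share SNPs), and `continuous` (non-negative per-SNP weights `a[k, m]`; the
#' component's genotype matrix is implicitly `X_k diag(sqrt(a_k))`).
#'
#' @param members List of `K` integer vectors: SNP indices in each component.
#' @param M Total number of SNPs.
#' @param mode One of "disjoint", "overlapping", "continuous".
#' @param weights For continuous mode, a list parallel to `members` of
#'   non-negative weights; ignored otherwise (taken as 1).
#' @param names Optional component names.
#' @return An object of class `"annotation_set"` with fields `K`, `M`, `mode`,
#'   `members`, `weights`, `sizes`, `names` and, in disjoint mode, `assign`.
#' @export
annotation_set <- function(members, M, mode = c("disjoint", "overlapping", "continuous"),
                           weights = NULL, names = NULL) {
  mode <- match.arg(mode)
  K <- length(members)
  if (K < 1L) stop("need at least one component")
  members <- lapply(members, as.integer)
  sizes <- vapply(members, length, integer(1))
  if (any(sizes < 1L)) stop("every component must contain at least one SNP")
  all_idx <- unlist(members)
  if (any(all_idx < 1L | all_idx > M)) stop("SNP index out of range")
  if (is.null(weights)) {
    weights <- lapply(members, function(s) rep(1, length(s)))
  } else {
    if (length(weights) != K ||
        any(vapply(weights, length, integer(1)) != sizes)) {
      stop("weights must parallel members")
    }
    bad <- which(vapply(weights, function(w) any(w < 0), logical(1)))
    if (length(bad)) {
      snp <- members[[bad[1]]][which(weights[[bad[1]]] < 0)[1]]
      stop("negative annotation weight at SNP ", snp, " (component ", bad[1], ")")
    }
  }
  assign <- NULL
  if (mode == "disjoint") {
    if (length(all_idx) != M || anyDuplicated(all_idx) || length(unique(all_idx)) != M) {
      stop("disjoint mode requires a set partition of all ", M, " SNPs")
    }
    assign <- integer(M)
    for (k in seq_len(K)) assign[members[[k]]] <- k
  }
  if (is.null(names)) names <- paste0("comp", seq_len(K))
  structure(list(K = K, M = as.integer(M), mode = mode, members = members,
                 weights = weights, sizes = sizes, names = names,
                 assign = assign),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d components over %d SNPs (%s mode)\n",
              x$K, x$M, x$mode))
  cat("component sizes:", paste(utils::head(x$sizes, 12), collapse = " "),
      if (x$K > 12) "..." else "", "\n")
  invisible(x)
}

#' In-sample LD scores
#'
#' The LD score of a SNP is the sum of its squared correlations with all SNPs
#' on the same chromosome within `window_bp` base pairs, including itself
#' (which contributes exactly 1, so the minimum score is 1).
#'
#' @param X Standardized genotype matrix (individuals x SNPs; each column sum
#'   0, sum of squares N).
#' @param bp Base-pair positions, non-decreasing within each chromosome.
#' @param chrom Chromosome labels (single chromosome assumed if NULL).
#' @param window_bp Window half-width in base pairs (default 1 Mb).
#' @param chunk Number of SNPs per BLAS chunk.
#' @return Numeric vector of per-SNP LD scores (>= 1).
#' @export
ld_scores <- function(X, bp, chrom = NULL, window_bp = 1e6, chunk = 512L) {
  n <- nrow(X)
  m <- ncol(X)
  if (length(bp) != m) stop("bp length must match ncol(X)")
  if (is.null(chrom)) chrom <- rep("1", m)
  if (window_bp <= 0) stop("window_bp must be positive")
  if (!all(tapply(bp, chrom, function(p) !is.unsorted(p)))) {
    stop("SNPs must be sorted by position within chromosome")
  }
  score <- numeric(m)
  for (ch in unique(chrom)) {
    cols <- which(chrom == ch)
    pb <- bp[cols]
    for (i0 in seq(1L, length(cols), by = chunk)) {
      i1 <- min(i0 + chunk - 1L, length(cols))
      lo <- findInterval(pb[i0] - window_bp - 0.5, pb) + 1L  # inclusive at |diff| == window
      hi <- findInterval(pb[i1] + window_bp, pb)
      R <- crossprod(X[, cols[lo:hi], drop = FALSE],
                     X[, cols[i0:i1], drop = FALSE]) / n
      inwin <- abs(outer(pb[lo:hi], pb[i0:i1], `-`)) <= window_bp
      score[cols[i0:i1]] <- colSums(R^2 * inwin)
    }
  }
  score
}

#' Disjoint MAF x score-quantile partition
#'
#' Builds the standard heritability-partitioning bins: MAF intervals given by
#' `maf_breaks` (left-closed, right-open, except the last which is closed at
#' 0.5) crossed with in-sample quantile bins of a per-SNP score (LD scores or
#' external weights such as LDAK weights). Ties at a quantile edge go to the
#' lower bin. Empty bins are dropped (with a message) so that no component is
#' size zero.
#'
#' With `maf_breaks = 0.05, n_score_bins = 4` this reproduces the common
#' 8-bin scheme (2 MAF bins x LD-score quartiles); with
#' `maf_breaks = c(0.01, 0.02, 0.03, 0.04, 0.05)` the 24-bin scheme.
#'
#' @param freq Counted-allele frequencies (MAF is `pmin(freq, 1 - freq)`).
#' @param scores Per-SNP scores, one per SNP.
#' @param maf_breaks Sorted interior MAF breakpoints in (0, 0.5]; empty vector
#'   for a single MAF bin.
#' @param n_score_bins Number of score quantile bins (1 for none).
#' @return A disjoint [annotation_set()].
#' @export
maf_ld_partition <- function(freq, scores = NULL, maf_breaks = 0.05,
                             n_score_bins = 4L) {
  M <- length(freq)
  maf <- pmin(freq, 1 - freq)
  if (length(maf_breaks) && (any(maf_breaks <= 0) || any(maf_breaks > 0.5))) {
    stop("maf_breaks must lie in (0, 0.5]")
  }
  mbin <- findInterval(maf, sort(maf_breaks)) + 1L  # [b_i, b_{i+1}) intervals
  n_maf <- length(maf_breaks) + 1L
  if (n_score_bins > 1L) {
    if (is.null(scores)) stop("scores required when n_score_bins > 1")
    if (length(scores) != M) stop("scores length must match freq")
    edges <- stats::quantile(scores, probs = seq_len(n_score_bins - 1L) / n_score_bins,
                             names = FALSE, type = 7)
    if (anyDuplicated(edges)) {
      warning("degenerate score quantiles: ties collapse some bins")
    }
    sbin <- 1L + vapply(scores, function(s) sum(s > edges), integer(1))
  } else {
    sbin <- rep(1L, M)
  }
  comp <- (mbin - 1L) * n_score_bins + sbin
  K_full <- n_maf * n_score_bins
  present <- sort(unique(comp))
  if (length(present) < K_full) {
    message(sprintf("dropping %d empty bin(s); K = %d",
                    K_full - length(present), length(present)))
  }
  remap <- match(comp, present)
  mnames <- character(length(present))
  mb <- (present - 1L) %/% n_score_bins + 1L
  sb <- (present - 1L) %% n_score_bins + 1L
  mnames <- sprintf("maf%d_ld%d", mb, sb)
  annotation_set(split(seq_len(M), remap), M = M, mode = "disjoint",
                 names = mnames)
}

#' Load an annotation file
#'
#' Whitespace-delimited table with one row per SNP (in BIM order) and one
#' column per annotation; an optional header names the components. Binary
#' mode expects values in \{0, 1\}; continuous mode non-negative reals.
#'
#' @param path File path.
#' @param mode "binary" (overlapping membership) or "continuous".
#' @param M Expected number of SNPs (row-count consistency check).
#' @param add_rest If TRUE, SNPs in no annotation are collected into a
#'   catch-all "rest" component; otherwise such SNPs are an error.
#' @return An [annotation_set()] in overlapping or continuous mode.
#' @export
read_annotations <- function(path, mode = c("binary", "continuous"), M = NULL,
                             add_rest = FALSE) {
  mode <- match.arg(mode)
  first <- strsplit(trimws(readLines(path, n = 1L)), "\\s+")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  tab <- utils::read.table(path, header = has_header)
  A <- as.matrix(tab)
  if (!is.null(M) && nrow(A) != M) {
    stop(sprintf("annotation rows (%d) do not match SNP count (%d)", nrow(A), M))
  }
  if (any(A < 0)) {
    bad <- which(rowSums(A < 0) > 0)[1]
    stop("negative annotation value at SNP row ", bad)
  }
  if (mode == "binary" && !all(A %in% c(0, 1))) {
    stop("binary mode requires values in {0, 1}")
  }
  members <- lapply(seq_len(ncol(A)), function(k) which(A[, k] > 0))
  weights <- if (mode == "continuous") {
    lapply(seq_len(ncol(A)), function(k) A[A[, k] > 0, k])
  } else NULL
  nm <- if (has_header) colnames(tab) else paste0("annot", seq_len(ncol(A)))
  uncovered <- which(rowSums(A > 0) == 0)
  if (length(uncovered)) {
    if (!add_rest) {
      stop(length(uncovered), " SNP(s) belong to no annotation; ",
           "use add_rest = TRUE for a catch-all component")
    }
    members <- c(members, list(uncovered))
    if (!is.null(weights)) weights <- c(weights, list(rep(1, length(uncovered))))
    nm <- c(nm, "rest")
  }
  annotation_set(members, M = nrow(A),
                 mode = if (mode == "binary") "overlapping" else "continuous",
                 weights = weights, names = nm)
}

#' Apply continuous annotation weights to a standardized block
#'
#' Returns `X_k diag(sqrt(a_k))` for the SNPs of component `k` present in the
#' block: column `m` is scaled by `sqrt(a[k, m])`.
#'
#' @param X Standardized block (individuals x SNPs).
#' @param idx Global SNP indices of the block's columns.
#' @param annot An [annotation_set()].
#' @param k Component index.
#' @return List with `X` (weighted columns) and `idx` (their global indices);
#'   columns of SNPs not in component `k` are omitted.
#' @export
apply_continuous_weights <- function(X, idx, annot, k) {
  pos <- match(idx, annot$members[[k]])
  keep <- which(!is.na(pos))
  w <- annot$weights[[k]][pos[keep]]
  list(X = sweep(X[, keep, drop = FALSE], 2L, sqrt(w), `*`),
       idx = idx[keep])
}

# Long-format (snp, component, weight) table sorted by snp index, used by the
# streaming accumulator to scatter block columns into components.
.annot_entries <- function(annot) {
  snp <- unlist(annot$members)
  comp <- rep.int(seq_len(annot$K), annot$sizes)
  w <- unlist(annot$weights)
  o <- order(snp)
  list(snp = snp[o], comp = comp[o], w = w[o])
}
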