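# PLINK 1 BED magic bytes: 0x6c 0x1b, then 0x01 for SNP-major layout.
.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

# 2-bit genotype codes -> counted-allele (allele-1) dosage.
# 00 = hom A1 (2 copies), 01 = missing, 10 = het (1), 11 = hom A2 (0).
.bed_decode_table <- local({
  tab <- matrix(NA_integer_, 256L, 4L)
  map <- c(2L, NA_integer_, 1L, 0L)
  for (v in 0:255) {
    for (i in 0:3) {
      tab[v + 1L, i + 1L] <- map[bitwAnd(bitwShiftR(v, 2L * i), 3L) + 1L]
    }
  }
  tab
})

.bed_encode_codes <- c(`0` = 3L, `1` = 2L, `2` = 0L)  # dosage -> 2-bit code

#' Read PLINK BIM/FAM metadata
#'
#' @param prefix Path prefix of a PLINK fileset (`prefix.bed/.bim/.fam`).
#' @return `read_bim()`: a data.frame with columns chrom, id, cm, bp, a1, a2.
#'   `read_fam()`: a data.frame with columns fid, iid, pat, mat, sex, pheno.
#' @export
read_bim <- function(prefix) {
  path <- paste0(prefix, ".bim")
  if (!file.exists(path)) stop("BIM file not found: ", path)
  bim <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "id", "cm", "bp", "a1", "a2")
  bim
}

#' @rdname read_bim
#' @export
read_fam <- function(prefix) {
  path <- paste0(prefix, ".fam")
  if (!file.exists(path)) stop("FAM file not found: ", path)
  fam <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "character",
                                          "character", "character", "character"))
  names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  fam
}

.bed_check <- function(prefix, n, m) {
  bed <- paste0(prefix, ".bed")
  if (!file.exists(bed)) stop("BED file not found: ", bed)
  con <- file(bed, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (length(magic) < 3L || !identical(magic, .BED_MAGIC)) {
    stop("not a SNP-major PLINK 1 BED file (bad magic bytes): ", bed)
  }
  bpp <- ceiling(n / 4)
  expected <- 3 + as.double(bpp) * m
  actual <- file.size(bed)
  if (actual != expected) {
    stop(sprintf(
      "BED size (%d bytes) inconsistent with FAM rows (N=%d) and BIM rows (M=%d)",
      actual, n, m))
  }
  invisible(TRUE)
}

# Decode `k` SNP-major records of `bpp` bytes into an n x k dosage matrix.
.bed_decode <- function(raw, n, bpp, k) {
  codes <- .bed_decode_table[as.integer(raw) + 1L, , drop = FALSE]
  # (i, byte, snp) array in sample-major order within each SNP record
  arr <- array(t(codes), dim = c(4L, bpp, k))
  matrix(arr, nrow = 4L * bpp)[seq_len(n), , drop = FALSE]
}

#' Stream genotypes from a PLINK fileset in SNP blocks
#'
#' Returns a genotype source: a list with fields `n`, `m`, `snps` (BIM table),
#' `fam`, and closures `next_block()` and `reset()`. Each `next_block()` call
#' yields `list(counts, idx)` where `counts` is an `n x b` integer matrix of
#' counted-allele dosages in \{0, 1, 2, NA\} (the counted allele is allele-1
#' of the BIM, the PLINK convention) and `idx` the global SNP indices, or
#' `NULL` once the file has been traversed. The `.bed` file is read once per
#' sweep, block by block.
#'
#' @param prefix Path prefix of the fileset.
#' @param block_size Maximum number of SNPs per block.
#' @return A genotype source (class `"geno_source"`).
#' @export
plink_source <- function(prefix, block_size = 1000L) {
  bim <- read_bim(prefix)
  fam <- read_fam(prefix)
  n <- nrow(fam)
  m <- nrow(bim)
  .bed_check(prefix, n, m)
  bpp <- ceiling(n / 4)
  bed <- paste0(prefix, ".bed")
  pos <- 0L
  next_block <- function() {
    if (pos >= m) return(NULL)
    k <- min(block_size, m - pos)
    con <- file(bed, "rb")
    on.exit(close(con))
    seek(con, 3 + as.double(bpp) * pos)
    raw <- readBin(con, "raw", bpp * k)
    counts <- .bed_decode(raw, n, bpp, k)
    idx <- pos + seq_len(k)
    pos <<- pos + k
    list(counts = counts, idx = idx)
  }
  reset <- function() pos <<- 0L
  structure(list(n = n, m = m, snps = bim, fam = fam,
                 next_block = next_block, reset = reset,
                 block_size = as.integer(block_size)),
            class = "geno_source")
}

#' In-memory genotype source
#'
#' Wraps an individuals-by-SNPs matrix of allele counts in the block-stream
#' interface of [plink_source()], so that downstream accumulation code is
#' agnostic to whether genotypes live on disk or in memory.
#'
#' @param counts Integer/numeric matrix, individuals x SNPs, values in
#'   \{0, 1, 2, NA\}.
#' @param snps Optional SNP metadata data.frame (columns chrom, id, bp at
#'   least); autogenerated if omitted (one chromosome, 1 kb spacing).
#' @param block_size Maximum number of SNPs per block.
#' @export
matrix_source <- function(counts, snps = NULL, block_size = 1000L) {
  n <- nrow(counts)
  m <- ncol(counts)
  if (is.null(snps)) {
    snps <- data.frame(chrom = "1",
                       id = paste0("snp", seq_len(m)),
                       cm = 0, bp = 1000L * seq_len(m),
                       a1 = "A", a2 = "C", stringsAsFactors = FALSE)
  }
  if (nrow(snps) != m) stop("snps metadata rows must equal ncol(counts)")
  pos <- 0L
  next_block <- function() {
    if (pos >= m) return(NULL)
    k <- min(block_size, m - pos)
    idx <- pos + seq_len(k)
    pos <<- pos + k
    list(counts = counts[, idx, drop = FALSE], idx = idx)
  }
  reset <- function() pos <<- 0L
  structure(list(n = n, m = m, snps = snps, fam = NULL,
                 next_block = next_block, reset = reset,
                 block_size = as.integer(block_size)),
            class = "geno_source")
}

.as_source <- function(genotypes, block_size = 1000L) {
  if (inherits(genotypes, "geno_source")) return(genotypes)
  if (is.matrix(genotypes)) return(matrix_source(genotypes, block_size = block_size))
  if (is.character(genotypes) && length(genotypes) == 1L) {
    return(plink_source(genotypes, block_size = block_size))
  }
  stop("genotypes must be a counts matrix, a PLINK prefix, or a geno_source")
}

#' Write a PLINK BED/BIM/FAM fileset
#'
#' @param counts Individuals x SNPs matrix of counted-allele dosages
#'   (0/1/2/NA); the counted allele is written as allele-1.
#' @param prefix Output path prefix.
#' @param snps Optional BIM-style data.frame (as from [read_bim()]).
#' @param fam Optional FAM-style data.frame.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(counts, prefix, snps = NULL, fam = NULL) {
  n <- nrow(counts)
  m <- ncol(counts)
  if (is.null(snps)) {
    snps <- data.frame(chrom = "1", id = paste0("snp", seq_len(m)),
                       cm = 0, bp = 1000L * seq_len(m),
                       a1 = "A", a2 = "C", stringsAsFactors = FALSE)
  }
  if (is.null(fam)) {
    fam <- data.frame(fid = paste0("F", seq_len(n)), iid = paste0("I", seq_len(n)),
                      pat = "0", mat = "0", sex = "0", pheno = "-9",
                      stringsAsFactors = FALSE)
  }
  stopifnot(nrow(snps) == m, nrow(fam) == n)
  bpp <- ceiling(n / 4)
  pad <- 4L * bpp - n
  x <- as.integer(counts)
  code <- integer(length(x))
  code[is.na(x)] <- 1L
  ok <- !is.na(x)
  code[ok] <- .bed_encode_codes[as.character(x[ok])]
  cm <- matrix(code, nrow = n)
  if (pad > 0) cm <- rbind(cm, matrix(3L, pad, m))  # pad codes are ignored on read
  dim(cm) <- NULL
  arr <- matrix(cm, nrow = 4L)  # 4 samples per byte, column-major over (byte, snp)
  bytes <- arr[1L, ] + 4L * arr[2L, ] + 16L * arr[3L, ] + 64L * arr[4L, ]
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(.BED_MAGIC, con)
  writeBin(as.raw(bytes), con)
  close(con)
  utils::write.table(snps[, c("chrom", "id", "cm", "bp", "a1", "a2")],
                     paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a whitespace-delimited phenotype or covariate file
#'
#' Expected layout is `FID IID value [value ...]` with an optional header
#' line. Missing values coded `NA` or `-9` are returned as `NA`.
#'
#' @param path File path.
#' @return data.frame with columns fid, iid and one numeric column per value
#'   column.
#' @export
read_pheno <- function(path) {
  first <- strsplit(trimws(readLines(path, n = 1L)), "\\s+")[[1]]
  if (length(first) < 3L) stop("phenotype file needs at least 3 columns (FID IID value)")
  has_header <- is.na(suppressWarnings(as.numeric(first[3]))) && first[3] != "NA"
  tab <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE,
                           na.strings = c("NA", "-9"))
  names(tab)[1:2] <- c("fid", "iid")
  for (j in seq(3, ncol(tab))) tab[[j]] <- as.numeric(tab[[j]])
  tab
}
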