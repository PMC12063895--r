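#' Write a genotype panel as PLINK bed/bim/fam
#'
#' SNP-major PLINK 1 binary format. The stored two-bit codes count a1
#' alleles: 00 = 2 copies, 10 = 1 copy, 11 = 0 copies, 01 = missing (never
#' emitted by the simulator).
#'
#' @param panel a \code{GenotypePanel}.
#' @param prefix path prefix; \code{.bed}, \code{.bim}, \code{.fam} are
#'   appended.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "GenotypePanel"))
  X <- panel$genotypes
  n <- nrow(X); m <- ncol(X)
  # genotype -> 2-bit code, pairs (bit1, bit2) little-endian within a byte
  code1 <- c(`0` = 1L, `1` = 0L, `2` = 0L)  # low bit
  code2 <- c(`0` = 1L, `1` = 1L, `2` = 0L)  # high bit
  npad <- ceiling(n / 4) * 4
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(m)) {
    g <- as.character(X[, j])
    bits <- integer(2 * npad)
    bits[seq(1, 2 * n, by = 2)] <- code1[g]
    bits[seq(2, 2 * n, by = 2)] <- code2[g]
    writeBin(packBits(as.integer(bits), type = "raw"), con)
  }
  v <- panel$variants
  utils::write.table(
    data.frame(v$chr, v$snp_id, 0, v$pos, v$a1, v$a2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(panel$individuals, panel$individuals, 0, 0, 0, -9),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam trio into a GenotypePanel
#'
#' @param prefix path prefix without extension.
#' @return A \code{GenotypePanel}; missing genotypes become \code{NA}.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           stringsAsFactors = FALSE)
  names(bim) <- c("chr", "snp_id", "cm", "pos", "a1", "a2")
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  bpl <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 3 + bpl * m)
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK 1 bed file")
  body <- raw[-(1:3)]
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8 * bpl)
  b1 <- bits[seq(1, 2 * n, by = 2), , drop = FALSE]
  b2 <- bits[seq(2, 2 * n, by = 2), , drop = FALSE]
  geno <- matrix(NA_integer_, n, m)
  geno[b1 == 0 & b2 == 0] <- 2L
  geno[b1 == 0 & b2 == 1] <- 1L
  geno[b1 == 1 & b2 == 1] <- 0L
  dimnames(geno) <- list(fam$V2, bim$snp_id)
  maf <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(maf, 1 - maf)
  panel <- list(genotypes = geno,
                variants = data.frame(snp_id = bim$snp_id, chr = bim$chr,
                                      pos = bim$pos, a1 = bim$a1, a2 = bim$a2,
                                      maf = maf, info = 1,
                                      stringsAsFactors = FALSE),
                individuals = fam$V2)
  class(panel) <- "GenotypePanel"
  panel
}

#' Write GWAS summary statistics as TSV
#'
#' Dialect: header SNP CHR BP A1 A2 BETA SE N FRQ, tab-separated.
#'
#' @param ss a \code{SummaryStats}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  r <- ss$records
  out <- data.frame(SNP = r$snp_id, CHR = r$chr, BP = r$pos, A1 = r$a1,
                    A2 = r$a2, BETA = r$beta, SE = r$se, N = r$n, FRQ = r$frq)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics from TSV
#'
#' @param path file with header SNP CHR BP A1 A2 BETA SE N FRQ.
#' @param trait_id label for the trait.
#' @return A \code{SummaryStats}.
#' @export
read_sumstats <- function(path, trait_id = basename(path)) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "N", "FRQ")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("summary-statistic file missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  rec <- data.frame(snp_id = as.character(d$SNP), chr = d$CHR, pos = d$BP,
                    a1 = toupper(as.character(d$A1)),
                    a2 = toupper(as.character(d$A2)),
                    beta = d$BETA, se = d$SE, z = d$BETA / d$SE, n = d$N,
                    frq = d$FRQ, flagged = FALSE, stringsAsFactors = FALSE)
  sumstats(rec, trait_id = trait_id)
}

#' Write a CellMatrix as MTX plus metadata tables
#'
#' Emits \code{matrix.mtx} (genes x cells), \code{genes.tsv} (one id per
#' line) and \code{cells.tsv} (cell_id, cell_type, group).
#'
#' @param cm a \code{CellMatrix}.
#' @param dir output directory, created if needed.
#' @return the directory, invisibly.
#' @export
write_mtx_dir <- function(cm, dir) {
  stopifnot(inherits(cm, "CellMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  writeLines(cm$genes, file.path(dir, "genes.tsv"))
  utils::write.table(cm$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a CellMatrix from an MTX directory
#'
#' @param dir directory with matrix.mtx, genes.tsv, cells.tsv.
#' @return A \code{CellMatrix}.
#' @export
read_mtx_dir <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- utils::read.table(file.path(dir, "cells.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  dimnames(counts) <- list(genes, cells$cell_id)
  cell_matrix(counts, cells)
}

#' Read a gene coordinate table
#'
#' BED-like TSV with header gene_id, chr, start, end (1-based inclusive).
#'
#' @param path input file.
#' @return data.frame with those columns.
#' @export
read_gene_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "chr", "start", "end")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(d$start > d$end)) stop("gene table has start > end")
  d
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors; the description is kept in the
#'   "description" attribute of each element.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    genes <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    attr(genes, "description") <- f[2]
    genes
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    paste(c(nm, if (is.null(desc)) "na" else desc, sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
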