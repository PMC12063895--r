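#' GWAS summary-statistics container
#'
#' @param records data.frame with columns snp_id, chr, pos, a1, a2, beta, se,
#'   z, n, frq (a \code{flagged} column is added when absent).
#' @param trait_id label for the trait.
#' @return A \code{SummaryStats}: list(records, trait_id, n_max).
#' @export
sumstats <- function(records, trait_id = "trait") {
  need <- c("snp_id", "chr", "pos", "a1", "a2", "beta", "se", "z", "n", "frq")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("summary-statistic records missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"flagged" %in% names(records)) records$flagged <- FALSE
  structure(list(records = records, trait_id = trait_id,
                 n_max = if (nrow(records)) max(records$n, na.rm = TRUE) else 0L),
            class = "SummaryStats")
}

#' @export
print.SummaryStats <- function(x, ...) {
  cat(sprintf("SummaryStats '%s': %d SNPs, n_max = %d\n",
              x$trait_id, nrow(x$records), x$n_max))
  invisible(x)
}

#' Quality-control filter for GWAS summary statistics
#'
#' Applies, in order: (i) keep autosomes 1-22; (ii) drop records observed in
#' fewer than \code{min_sample_frac} of the trait's maximum reported N;
#' (iii) drop alleles outside A/C/G/T; (iv) drop records whose summary
#' variance is anomalous (non-finite beta or se^2 <= 0); (v) drop se <= 0;
#' (vi) drop MAF below \code{min_maf}. Chromosome labels "chrN" are
#' normalized to N before rule (i).
#'
#' @param ss a \code{SummaryStats}.
#' @param min_sample_frac minimum per-SNP sample fraction relative to n_max.
#' @param min_maf minimum minor-allele frequency.
#' @return list(ss = filtered \code{SummaryStats}, report = data.frame of
#'   per-rule removal counts).
#' @export
qc_filter <- function(ss, min_sample_frac = 0.7, min_maf = 0.001) {
  stopifnot(inherits(ss, "SummaryStats"))
  r <- ss$records
  chr_norm <- sub("^chr", "", as.character(r$chr), ignore.case = TRUE)
  chr_num <- suppressWarnings(as.integer(chr_norm))
  rules <- list(
    autosome = !is.na(chr_num) & chr_num >= 1 & chr_num <= 22,
    sample_fraction = r$n >= min_sample_frac * ss$n_max,
    alleles = toupper(r$a1) %in% c("A", "C", "G", "T") &
      toupper(r$a2) %in% c("A", "C", "G", "T"),
    variance = is.finite(r$beta) & is.finite(r$se) & r$se^2 > 0,
    se_positive = is.finite(r$se) & r$se > 0,
    maf = pmin(r$frq, 1 - r$frq) >= min_maf
  )
  keep <- rep(TRUE, nrow(r))
  removed <- integer(length(rules))
  for (i in seq_along(rules)) {
    ok <- rules[[i]] & !is.na(rules[[i]])
    removed[i] <- sum(keep & !ok)
    keep <- keep & ok
  }
  out <- r[keep, , drop = FALSE]
  out$chr <- chr_num[keep]
  filtered <- sumstats(out, trait_id = ss$trait_id)
  filtered$n_max <- ss$n_max  # denominator is the pre-QC maximum N
  report <- data.frame(rule = names(rules), removed = removed,
                       stringsAsFactors = FALSE)
  list(ss = filtered, report = report,
       n_in = nrow(r), n_out = nrow(out))
}

#' LD scores with small-sample bias correction
#'
#' For SNP j, l_j = sum over SNPs k within \code{window_bp} on the same
#' chromosome (including j itself) of r2_adj(j,k), where
#' r2_adj = r2 - (1 - r2) / (n - 2). Bias-corrected scores may dip below 1.
#'
#' @param panel a \code{GenotypePanel} (>= 2 individuals).
#' @param window_bp window half-width in base pairs.
#' @return data.frame (snp_id, ld_score) with attribute \code{window_bp}.
#' @export
compute_ld_scores <- function(panel, window_bp = 1e6) {
  stopifnot(inherits(panel, "GenotypePanel"))
  if (window_bp <= 0) stop("window_bp must be > 0")
  X <- panel$genotypes
  n <- nrow(X)
  if (n < 2) stop("panel must have >= 2 individuals")
  v <- panel$variants
  l <- numeric(ncol(X))
  for (ch in unique(v$chr)) {
    idx <- which(v$chr == ch)
    pos <- v$pos[idx]
    R2 <- stats::cor(X[, idx, drop = FALSE])^2
    R2adj <- R2 - (1 - R2) / (n - 2)
    inwin <- abs(outer(pos, pos, `-`)) <= window_bp
    l[idx] <- rowSums(R2adj * inwin)
  }
  out <- data.frame(snp_id = v$snp_id, ld_score = l, stringsAsFactors = FALSE)
  attr(out, "window_bp") <- window_bp
  out
}

#' LD-score-regression heritability estimate
#'
#' Weighted least squares of chi^2_j = z_j^2 on N_j * l_j / M with weights
#' 1 / max(l_j, 1); h2 is the slope and the regression intercept is
#' reported. The standard error comes from a delete-one block jackknife over
#' contiguous SNP blocks.
#'
#' @param ss a \code{SummaryStats} (QC-filtered).
#' @param ld LD-score table from \code{\link{compute_ld_scores}} (or any
#'   data.frame with snp_id, ld_score).
#' @param M number of SNPs the LD scores were computed over; defaults to
#'   \code{nrow(ld)}.
#' @param n_blocks jackknife blocks.
#' @return A \code{HeritabilityEstimate}: list(h2, intercept, se_h2, M,
#'   n_snps, passed_gate).
#' @export
estimate_h2_ldsc <- function(ss, ld, M = nrow(ld), n_blocks = 20) {
  stopifnot(inherits(ss, "SummaryStats"))
  r <- merge(ss$records, ld, by = "snp_id", sort = FALSE)
  r <- r[is.finite(r$z) & is.finite(r$ld_score), , drop = FALSE]
  if (nrow(r) < 50)
    stop("fewer than 50 SNPs overlap the LD scores; estimate would be unstable")
  chi2 <- r$z^2
  x <- r$n * r$ld_score / M
  w <- 1 / pmax(r$ld_score, 1)

  if (stats::var(chi2) == 0)  # constant response: slope is exactly 0
    return(structure(list(h2 = 0, intercept = chi2[1], se_h2 = 0, M = M,
                          n_snps = nrow(r), passed_gate = NA),
                     class = "HeritabilityEstimate"))
  if (stats::var(x) == 0)
    stop("LD-score predictor is constant; slope is not identifiable")

  wls <- function(keep) {
    fit <- stats::lm.wfit(cbind(1, x[keep]), chi2[keep], w[keep])
    fit$coefficients
  }
  co <- wls(rep(TRUE, length(x)))
  # delete-one-block jackknife over contiguous SNP blocks
  blk <- as.integer(cut(seq_along(x), breaks = n_blocks, labels = FALSE))
  th <- vapply(seq_len(n_blocks), function(b) wls(blk != b)[2], numeric(1))
  nb <- n_blocks
  se_h2 <- sqrt((nb - 1) / nb * sum((th - mean(th))^2))

  structure(list(h2 = unname(co[2]), intercept = unname(co[1]),
                 se_h2 = se_h2, M = M, n_snps = nrow(r),
                 passed_gate = NA),
            class = "HeritabilityEstimate")
}

#' @export
print.HeritabilityEstimate <- function(x, ...) {
  cat(sprintf("h2 = %.4f (se %.4f), intercept = %.4f, M = %d, SNPs = %d\n",
              x$h2, x$se_h2, x$intercept, x$M, x$n_snps))
  invisible(x)
}

#' Heritability gate
#'
#' TRUE iff the point estimate exceeds the threshold strictly; traits
#' failing the gate are excluded from downstream stages.
#'
#' @param est a \code{HeritabilityEstimate} (or a bare h2 value).
#' @param threshold gate threshold (strict ">").
#' @return logical flag.
#' @export
heritability_gate <- function(est, threshold = 0.1) {
  h2 <- if (inherits(est, "HeritabilityEstimate")) est$h2 else est
  h2 > threshold
}
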