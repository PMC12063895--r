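#' Genotype QC for eQTL model training
#'
#' Removes SNPs with imputation info below \code{min_info} or MAF below
#' \code{min_maf}.
#'
#' @param panel a \code{GenotypePanel} (variants must carry an \code{info}
#'   column; the simulator sets it to 1).
#' @param min_info minimum imputation info score.
#' @param min_maf minimum minor-allele frequency.
#' @return list(panel = filtered panel, report = per-rule removal counts).
#' @export
genotype_qc_eqtl <- function(panel, min_info = 0.7, min_maf = 0.01) {
  stopifnot(inherits(panel, "GenotypePanel"))
  v <- panel$variants
  if (is.null(v$info)) stop("variant table lacks an info column")
  frq <- colMeans(panel$genotypes) / 2
  maf <- pmin(frq, 1 - frq)
  bad_info <- v$info < min_info
  bad_maf <- !bad_info & maf < min_maf
  keep <- !(bad_info | maf < min_maf)
  out <- panel
  out$genotypes <- panel$genotypes[, keep, drop = FALSE]
  out$variants <- v[keep, , drop = FALSE]
  list(panel = out,
       report = data.frame(rule = c("info", "maf"),
                           removed = c(sum(bad_info), sum(bad_maf)),
                           stringsAsFactors = FALSE))
}

#' Extract cis SNPs for a gene
#'
#' SNPs on the gene's chromosome with position in
#' [start - cis_kb*1000, end + cis_kb*1000] (closed interval).
#'
#' @param panel a \code{GenotypePanel}.
#' @param gene one-row gene record (gene_id, chr, start, end).
#' @param cis_kb window half-width in kb.
#' @return the cis sub-panel, or NULL (with a message) when no SNP falls in
#'   the window.
#' @export
extract_cis_snps <- function(panel, gene, cis_kb = 500) {
  stopifnot(inherits(panel, "GenotypePanel"))
  v <- panel$variants
  lo <- gene$start - cis_kb * 1000
  hi <- gene$end + cis_kb * 1000
  keep <- v$chr == gene$chr & v$pos >= lo & v$pos <= hi
  if (!any(keep)) {
    message("gene ", gene$gene_id, " has no cis SNPs; skipped")
    return(NULL)
  }
  out <- panel
  out$genotypes <- panel$genotypes[, keep, drop = FALSE]
  out$variants <- v[keep, , drop = FALSE]
  out
}

# quadratic-form helper for Haseman-Elston: sum_{i<j} A_ij y_i y_j
he_numerator <- function(A, Y) {
  # Y: n x r matrix of (standardized) phenotypes; returns length-r vector
  q <- colSums(Y * (A %*% Y))
  d <- colSums(Y^2 * diag(A))
  (q - d) / 2
}

#' Cis heritability by Haseman-Elston regression
#'
#' Builds the cis genetic-relatedness matrix A = X X' / m on standardized
#' dosages and regresses off-diagonal products of the standardized
#' expression on the corresponding A entries; the slope, clipped to [0, 1],
#' estimates cis-h2. The p-value comes from permuting expression.
#'
#' @param sub cis sub-panel (\code{GenotypePanel}).
#' @param expr per-individual expression vector.
#' @param n_perm permutations for the p-value.
#' @param seed integer seed for the permutations.
#' @return list(cis_h2, p, slope_raw).
#' @export
estimate_cis_h2 <- function(sub, expr, n_perm = 200, seed = 1) {
  stopifnot(inherits(sub, "GenotypePanel"))
  n <- nrow(sub$genotypes)
  if (length(expr) != n) stop("expression length must match individuals")
  if (stats::sd(expr) == 0) stop("expression is constant")
  Xs <- scale(sub$genotypes)
  Xs[!is.finite(Xs)] <- 0
  A <- tcrossprod(Xs) / ncol(Xs)
  y <- as.numeric(scale(expr))
  denom <- (sum(A^2) - sum(diag(A)^2)) / 2
  if (denom <= 0) stop("degenerate cis relatedness matrix")
  num_obs <- he_numerator(A, matrix(y, ncol = 1))
  slope <- num_obs / denom
  set.seed(as.integer(seed))
  Yp <- vapply(seq_len(n_perm), function(i) y[sample.int(n)],
               numeric(n))
  num_perm <- he_numerator(A, Yp)
  p <- (1 + sum(num_perm / denom >= slope)) / (1 + n_perm)
  list(cis_h2 = min(max(slope, 0), 1), p = p, slope_raw = slope)
}

# signed cross-validated r2: sign(cor) * cor^2, 0 for degenerate predictions
signed_r2 <- function(pred, y) {
  if (stats::sd(pred) == 0 || stats::sd(y) == 0) return(0)
  r <- stats::cor(pred, y)
  if (!is.finite(r)) return(0)
  sign(r) * r^2
}

fit_top1 <- function(X, y) {
  # single best marginal SNP, OLS slope on that SNP
  xm <- colMeans(X); ym <- mean(y)
  sxx <- colSums(X^2) - nrow(X) * xm^2
  sxy <- drop(crossprod(X, y)) - nrow(X) * xm * ym
  ok <- sxx > 0
  r2 <- rep(-Inf, ncol(X))
  r2[ok] <- sxy[ok]^2 / sxx[ok]
  j <- which.max(r2)
  w <- numeric(ncol(X))
  w[j] <- sxy[j] / sxx[j]
  b0 <- ym - w[j] * xm[j]
  list(weights = w, intercept = b0)
}

fit_glmnet_method <- function(X, y, alpha, nfolds) {
  cv <- glmnet::cv.glmnet(X, y, alpha = alpha, nfolds = nfolds,
                          standardize = TRUE)
  co <- as.numeric(stats::coef(cv, s = "lambda.min"))
  list(weights = co[-1], intercept = co[1])
}

#' Train per-gene cis-eQTL weight models
#'
#' Four learners are fitted -- top1 (best marginal SNP), ridge_blup (ridge
#' regression), lasso and enet (elastic net, alpha = 0.5); the glmnet
#' penalties are chosen by inner cross-validation. cv_r2 is the signed
#' squared correlation between out-of-fold predictions and expression over
#' \code{folds} outer folds; the best method maximizes cv_r2 (ties broken
#' toward the later entry in top1 < ridge_blup < lasso < enet). Final
#' weights are refit on all samples. Models whose cv_r2 are all <= 0, or
#' that fail the cis-h2 permutation gate, are rejected (NULL with a
#' message).
#'
#' @param sub cis sub-panel.
#' @param expr per-individual expression vector.
#' @param folds outer CV folds.
#' @param seed integer seed (fold assignment and permutation gate).
#' @param gene_id,cell_type labels carried into the model.
#' @param h2_gate_p cis-h2 permutation-p gate (model skipped when the gate
#'   fails); set to 1 to disable.
#' @param inner_nfolds folds for the glmnet penalty search.
#' @return A \code{CisModel} or NULL when the gene is rejected.
#' @export
fit_weights <- function(sub, expr, folds = 5, seed = 1, gene_id = "gene",
                        cell_type = "all", h2_gate_p = 0.05,
                        inner_nfolds = 5) {
  stopifnot(inherits(sub, "GenotypePanel"))
  n <- nrow(sub$genotypes)
  X <- sub$genotypes
  storage.mode(X) <- "double"
  y <- as.numeric(expr)

  he <- estimate_cis_h2(sub, y, seed = seed)
  if (he$p >= h2_gate_p) {
    message("gene ", gene_id, ": cis-h2 gate failed (p = ",
            signif(he$p, 3), "); skipped")
    return(NULL)
  }

  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(folds), length.out = n))
  methods_ <- c("top1", "ridge_blup", "lasso", "enet")
  alphas <- c(ridge_blup = 0, lasso = 1, enet = 0.5)
  oof <- matrix(NA_real_, n, length(methods_),
                dimnames = list(NULL, methods_))
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    t1 <- fit_top1(Xtr, ytr)
    oof[te, "top1"] <- X[te, , drop = FALSE] %*% t1$weights + t1$intercept
    for (m in names(alphas)) {
      fm <- fit_glmnet_method(Xtr, ytr, alphas[[m]], inner_nfolds)
      oof[te, m] <- X[te, , drop = FALSE] %*% fm$weights + fm$intercept
    }
  }
  cv_r2 <- apply(oof, 2, signed_r2, y = y)
  if (all(cv_r2 <= 0)) {
    message("gene ", gene_id, ": no method achieves cv_r2 > 0; rejected")
    return(NULL)
  }
  best_idx <- max(which(cv_r2 == max(cv_r2)))
  best <- methods_[best_idx]

  final <- list(
    top1 = fit_top1(X, y)$weights,
    ridge_blup = fit_glmnet_method(X, y, 0, inner_nfolds)$weights,
    lasso = fit_glmnet_method(X, y, 1, inner_nfolds)$weights,
    enet = fit_glmnet_method(X, y, 0.5, inner_nfolds)$weights
  )
  structure(list(gene_id = gene_id, cell_type = cell_type,
                 snp_ids = sub$variants$snp_id,
                 a1 = sub$variants$a1, a2 = sub$variants$a2,
                 weights = final, cv_r2 = cv_r2, best_method = best,
                 cis_h2 = he$cis_h2, cis_h2_p = he$p),
            class = "CisModel")
}

#' @export
print.CisModel <- function(x, ...) {
  cat(sprintf("CisModel %s / %s: %d SNPs, best = %s (cv_r2 = %.3f), cis-h2 = %.3f (p = %.3g)\n",
              x$gene_id, x$cell_type, length(x$snp_ids), x$best_method,
              max(x$cv_r2), x$cis_h2, x$cis_h2_p))
  invisible(x)
}

#' Summary-based TWAS association
#'
#' z_twas = w' z / sqrt(w' R w) where w are the model's weights (best
#' method), z the GWAS z-scores of the model SNPs and R the reference LD.
#' Model SNPs are matched to the summary statistics by id; a swapped a1/a2
#' pair flips the z sign, other allele mismatches drop the SNP with a
#' warning. The variance denominator is floored at 1e-8 with a warning when
#' near-singular.
#'
#' @param model a \code{CisModel}.
#' @param ss a \code{SummaryStats}.
#' @param R_ref LD correlation matrix over the model SNPs (reference panel).
#' @param method which weight vector to use; default the model's best.
#' @return one-row data.frame: gene_id, cell_type, trait_id, z_twas, p.
#' @export
twas_assoc <- function(model, ss, R_ref, method = model$best_method) {
  stopifnot(inherits(model, "CisModel"), inherits(ss, "SummaryStats"))
  w <- model$weights[[method]]
  r <- ss$records
  i <- match(model$snp_ids, r$snp_id)
  z <- rep(NA_real_, length(w))
  found <- !is.na(i)
  same <- found & toupper(model$a1) == toupper(r$a1[i]) &
    toupper(model$a2) == toupper(r$a2[i])
  swap <- found & toupper(model$a1) == toupper(r$a2[i]) &
    toupper(model$a2) == toupper(r$a1[i])
  z[same] <- r$z[i[same]]
  z[swap] <- -r$z[i[swap]]
  bad <- found & !same & !swap
  if (any(bad))
    warning(sum(bad), " model SNP(s) with irreconcilable alleles dropped")
  keep <- is.finite(z)
  if (!any(keep)) stop("no model SNPs could be matched to the summary statistics")
  if (!all(keep)) {
    if (any(found & !keep & !bad) || any(!found))
      warning(sum(!keep) - sum(bad), " model SNP(s) missing from the summary statistics dropped")
    w <- w[keep]
    z <- z[keep]
    R_ref <- R_ref[keep, keep, drop = FALSE]
  }
  den2 <- drop(t(w) %*% R_ref %*% w)
  if (den2 < 1e-8) {
    warning("near-singular TWAS variance; denominator floored at 1e-8")
    den2 <- 1e-8
  }
  z_twas <- sum(w * z) / sqrt(den2)
  data.frame(gene_id = model$gene_id, cell_type = model$cell_type,
             trait_id = ss$trait_id, z_twas = z_twas,
             p = 2 * stats::pnorm(-abs(z_twas)), stringsAsFactors = FALSE)
}

#' Pseudo-bulk expression from single cells
#'
#' Per (individual x cell type), the mean of normalized expression over that
#' individual's cells of the type, inverse-normal transformed across
#' individuals (Blom offset 3/8) so each gene's pseudo-bulk phenotype is
#' Gaussian before model fitting.
#'
#' @param cm a normalized \code{CellMatrix}.
#' @param individual_ids per-cell individual labels aligned with the cells.
#' @param cell_type the cell type to aggregate.
#' @return matrix genes x individuals of inverse-normal-transformed means.
#' @export
pseudobulk_from_cells <- function(cm, individual_ids, cell_type) {
  stopifnot(inherits(cm, "CellMatrix"))
  if (is.null(cm$norm)) stop("run normalize_expression first")
  sel <- cm$cells$cell_type == cell_type
  if (!any(sel)) stop("no cells of type ", cell_type)
  ids <- individual_ids[sel]
  Xn <- cm$norm[, sel, drop = FALSE]
  uid <- sort(unique(ids))
  agg <- vapply(uid, function(u)
    Matrix::rowMeans(Xn[, ids == u, drop = FALSE]), numeric(nrow(Xn)))
  int <- function(x) {
    r <- rank(x, ties.method = "average")
    stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  }
  out <- t(apply(agg, 1, int))
  dimnames(out) <- list(rownames(Xn), uid)
  out
}

#' BH adjustment of a TWAS result table
#'
#' BH over all (gene x cell type x trait) tests; populates both the nominal
#' (p < 0.05) and study-wide (p_adj < 0.05) significance flags.
#'
#' @param results data.frame with a \code{p} column (rows from
#'   \code{\link{twas_assoc}}).
#' @return the table with p_adj, nominal_sig and study_sig columns.
#' @export
adjust_results <- function(results) {
  results$p_adj <- stats::p.adjust(results$p, method = "BH")
  results$nominal_sig <- results$p < 0.05
  results$study_sig <- results$p_adj < 0.05
  results
}
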