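#' Cell and gene quality control
#'
#' Rules applied in order: remove cells expressing fewer than
#' \code{min_genes} genes; remove cells with total UMI >= \code{max_umi};
#' remove cells whose mitochondrial fraction of total UMI is
#' >= \code{max_mito_frac}; then remove genes expressed in fewer than
#' \code{min_cells_per_gene} cells.
#'
#' @param raw a \code{CellMatrix} of raw counts.
#' @param min_genes minimum expressed genes per cell.
#' @param max_umi UMI ceiling (cells at or above it are removed).
#' @param max_mito_frac mitochondrial-fraction ceiling.
#' @param min_cells_per_gene minimum cells per retained gene.
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @return list(cm = filtered \code{CellMatrix}, report = per-rule removal
#'   tallies).
#' @export
qc_cells <- function(raw, min_genes = 200, max_umi = 20000,
                     max_mito_frac = 0.15, min_cells_per_gene = 3,
                     mito_prefix = "MT-") {
  stopifnot(inherits(raw, "CellMatrix"))
  counts <- raw$counts
  genes_per_cell <- Matrix::colSums(counts > 0)
  total_umi <- Matrix::colSums(counts)
  mito <- startsWith(raw$genes, mito_prefix)
  mito_frac <- if (any(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total_umi, 1)
  else rep(0, ncol(counts))

  keep <- rep(TRUE, ncol(counts))
  rm_genes <- sum(keep & genes_per_cell < min_genes)
  keep <- keep & genes_per_cell >= min_genes
  rm_umi <- sum(keep & total_umi >= max_umi)
  keep <- keep & total_umi < max_umi
  rm_mito <- sum(keep & mito_frac >= max_mito_frac)
  keep <- keep & mito_frac < max_mito_frac
  if (!any(keep)) stop("no cells remain after quality control")
  cm <- subset_cells(raw, keep)

  cells_per_gene <- Matrix::rowSums(cm$counts > 0)
  gkeep <- cells_per_gene >= min_cells_per_gene
  rm_g <- sum(!gkeep)
  if (!any(gkeep)) stop("no genes remain after quality control")
  cm <- subset_genes(cm, gkeep)

  list(cm = cm,
       report = data.frame(
         rule = c("min_genes_per_cell", "max_umi", "max_mito_frac",
                  "min_cells_per_gene"),
         removed = c(rm_genes, rm_umi, rm_mito, rm_g),
         stringsAsFactors = FALSE))
}

#' Exclude cell subtypes
#'
#' @param cm a \code{CellMatrix}.
#' @param drop character vector of cell_type labels to remove.
#' @return list(cm, n_removed).
#' @export
exclude_subtypes <- function(cm, drop) {
  stopifnot(inherits(cm, "CellMatrix"))
  have <- unique(cm$cells$cell_type)
  bad <- setdiff(drop, have)
  if (length(bad))
    stop("unknown cell type(s): ", paste(bad, collapse = ", "),
         "; valid labels are: ", paste(have, collapse = ", "))
  keep <- !(cm$cells$cell_type %in% drop)
  if (!any(keep)) stop("excluding these subtypes would remove every cell")
  list(cm = subset_cells(cm, keep), n_removed = sum(!keep))
}

#' Merge cell subtypes into coarser labels
#'
#' @param cm a \code{CellMatrix}.
#' @param mapping data.frame (source, target); must cover every observed
#'   cell_type label.
#' @return the \code{CellMatrix} with a \code{merged_type} metadata column
#'   and cell_type replaced by the target labels.
#' @export
merge_subtypes <- function(cm, mapping) {
  stopifnot(inherits(cm, "CellMatrix"))
  i <- match(cm$cells$cell_type, mapping$source)
  if (anyNA(i))
    stop("unmapped cell type(s): ",
         paste(unique(cm$cells$cell_type[is.na(i)]), collapse = ", "))
  cm$cells$merged_type <- mapping$target[i]
  cm$cells$cell_type <- mapping$target[i]
  cm
}

#' Normalize expression to log1p counts-per-10k
#'
#' X_cg = log(1 + 1e4 * count / cell_total). Deterministic; errors on
#' zero-total cells (remove them with \code{\link{qc_cells}} first).
#'
#' @param cm a \code{CellMatrix}.
#' @return the \code{CellMatrix} with the normalized view in \code{$norm}.
#' @export
normalize_expression <- function(cm) {
  stopifnot(inherits(cm, "CellMatrix"))
  tot <- Matrix::colSums(cm$counts)
  if (any(tot == 0)) stop("zero-total cell(s) present; run qc_cells first")
  norm <- cm$counts %*% Matrix::Diagonal(x = 1e4 / tot)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(cm$counts)
  cm$norm <- methods::as(norm, "CsparseMatrix")
  cm
}

# per-gene mean and variance of a genes x cells sparse matrix
gene_mean_var <- function(X) {
  n <- ncol(X)
  mu <- Matrix::rowMeans(X)
  v <- (Matrix::rowSums(X^2) - n * mu^2) / (n - 1)
  list(mean = mu, var = pmax(v, 0))
}

# equal-size bins by value; identical values share a bin (ties.method "min")
bin_by_value <- function(x, n_bins) {
  n_bins <- max(1L, min(n_bins, length(unique(x))))
  rk <- rank(x, ties.method = "min")
  bin <- ceiling(rk / length(x) * n_bins)
  pmin(pmax(bin, 1L), n_bins)
}

#' Estimate gene-specific technical noise
#'
#' Genes are binned into \code{n_bins} equal-size bins by mean normalized
#' expression; sigma_tech,g is the square root of the bin-median variance,
#' floored at 1e-4 (so the minimum sigma is 1e-2). Genes with identical
#' means share a bin and hence a sigma.
#'
#' @param X normalized genes x cells matrix (the \code{$norm} view).
#' @param n_bins number of mean-expression bins.
#' @return A \code{TechNoiseModel}: list(sigma_tech named by gene, bins,
#'   n_bins).
#' @export
estimate_tech_noise <- function(X, n_bins = 20) {
  if (ncol(X) < 2) stop("need >= 2 cells to estimate technical noise")
  mv <- gene_mean_var(X)
  bin <- bin_by_value(mv$mean, n_bins)
  med <- tapply(mv$var, bin, stats::median)
  sigma <- sqrt(pmax(med[as.character(bin)], 1e-4))
  structure(list(sigma_tech = stats::setNames(as.numeric(sigma), rownames(X)),
                 bins = bin, n_bins = n_bins),
            class = "TechNoiseModel")
}

# resolve gene set against the matrix, clipping negative weights at 0
prepare_weights <- function(X, gs, noise) {
  genes <- intersect(gs$genes, rownames(X))
  missing <- setdiff(gs$genes, rownames(X))
  if (length(missing))
    warning(length(missing), " disease gene(s) absent from the matrix were dropped")
  if (!length(genes)) stop("no disease genes present in the expression matrix")
  w <- gs$weights[genes]
  if (any(w < 0)) {
    message(sum(w < 0), " negative gene weight(s) clipped at 0")
    w <- pmax(w, 0)
  }
  list(genes = genes, omega = w,
       sigma = noise$sigma_tech[genes])
}

#' Raw per-cell disease score
#'
#' S_c = sum_g omega_g * sigma_tech,g^-1 * X_cg / sum_g omega_g *
#' sigma_tech,g^-1 over the disease gene set G: a weighted average of
#' normalized expression, down-weighting technically noisy genes. Negative
#' omega_g are clipped at 0 (with a message).
#'
#' @param X normalized genes x cells matrix.
#' @param gs a \code{DiseaseGeneSet}.
#' @param noise a \code{TechNoiseModel} fitted on X.
#' @return numeric vector of raw scores, one per cell.
#' @export
raw_disease_score <- function(X, gs, noise) {
  pw <- prepare_weights(X, gs, noise)
  w <- pw$omega / pw$sigma
  den <- sum(w)
  if (den == 0) stop("score denominator is 0: all effective weights cancel")
  as.numeric(Matrix::crossprod(X[pw$genes, , drop = FALSE], w)) / den
}

#' Monte-Carlo matched control scores
#'
#' All genes are binned on (mean-expression x variance); for each of B
#' draws every disease gene is replaced by a gene sampled uniformly from its
#' (mean-bin x variance-bin) cell, carrying the disease gene's omega (the
#' control gene contributes its own sigma_tech). The raw score is then
#' computed per draw. Deterministic given \code{seed}. Empty matching cells
#' fall back to the nearest nonempty mean bin within the variance bin (with
#' a warning).
#'
#' @param X normalized genes x cells matrix.
#' @param gs a \code{DiseaseGeneSet}.
#' @param noise a \code{TechNoiseModel}.
#' @param B number of Monte-Carlo control sets.
#' @param n_mean_bins,n_var_bins matching-bin resolution.
#' @param seed integer seed.
#' @param pool optional restriction of the control candidate pool (gene
#'   ids); default all genes in X.
#' @return A \code{ControlScores}: list(S_ctrl n_cell x B matrix, B, bins).
#' @export
sample_control_scores <- function(X, gs, noise, B = 1000, n_mean_bins = 20,
                                  n_var_bins = 5, seed = 1, pool = NULL) {
  if (B < 1) stop("B must be >= 1")
  pw <- prepare_weights(X, gs, noise)
  mv <- gene_mean_var(X)
  all_genes <- rownames(X)
  if (is.null(pool)) pool <- all_genes
  mbin <- bin_by_value(mv$mean, n_mean_bins)
  vbin <- bin_by_value(mv$var, n_var_bins)
  names(mbin) <- names(vbin) <- all_genes
  in_pool <- all_genes %in% pool

  cell_key <- stats::setNames(paste(mbin, vbin), all_genes)
  pool_by_cell <- split(which(in_pool), cell_key[in_pool])

  # candidate indices per disease gene
  cands <- lapply(pw$genes, function(g) {
    key <- cell_key[[g]]
    hit <- pool_by_cell[[key]]
    if (!is.null(hit) && length(hit)) return(hit)
    # nearest nonempty mean bin within the same variance bin, then anywhere
    warning("empty matching bin for gene ", g,
            "; falling back to nearest nonempty mean bin")
    vb <- vbin[[g]]
    same_v <- which(in_pool & vbin == vb)
    if (length(same_v)) {
      d <- abs(mbin[same_v] - mbin[[g]])
      return(same_v[d == min(d)])
    }
    which(in_pool)
  })

  set.seed(as.integer(seed))
  sigma_all <- noise$sigma_tech
  S_ctrl <- matrix(NA_real_, ncol(X), B)
  k <- length(pw$genes)
  for (b in seq_len(B)) {
    pick <- vapply(cands, function(ix)
      if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)], integer(1))
    w <- pw$omega / sigma_all[pick]
    den <- sum(w)
    if (den == 0) stop("control score denominator is 0")
    S_ctrl[, b] <- as.numeric(
      Matrix::crossprod(X[pick, , drop = FALSE], w)) / den
  }
  structure(list(S_ctrl = S_ctrl, B = B,
                 bins = list(mean = mbin, var = vbin)),
            class = "ControlScores")
}

#' Empirical cell-level p-values from pooled normalized control scores
#'
#' Each cell's raw score is centred and scaled by the mean and sd of its own
#' B control scores; control scores are normalized the same way (per cell).
#' Then P_c = (1 + #\{(c', b): S_c <= S_ctrl(c', b)\}) / (1 + n_cell * B)
#' on the normalized scale, followed by BH adjustment across cells.
#'
#' @param S raw score vector.
#' @param ctrl a \code{ControlScores} computed on the same cells.
#' @return A \code{ScoreResult} data.frame: raw_score, norm_score, p,
#'   p_adj, significant (p_adj < 0.05).
#' @export
cell_pvalues <- function(S, ctrl) {
  stopifnot(inherits(ctrl, "ControlScores"))
  C <- ctrl$S_ctrl
  if (length(S) != nrow(C)) stop("scores and control scores disagree on cells")
  B <- ctrl$B
  if (B >= 2) {
    mu <- rowMeans(C)
    sd <- pmax(apply(C, 1, stats::sd), 1e-12)
    Sn <- (S - mu) / sd
    Cn <- (C - mu) / sd
  } else {
    Sn <- S
    Cn <- C
  }
  pool <- sort(as.numeric(Cn))
  N <- length(pool)
  # count of pooled values >= Sn[c]  (1[S_c <= ctrl])
  cnt_lt <- findInterval(Sn, pool, left.open = TRUE)
  p <- (1 + (N - cnt_lt)) / (1 + N)
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(raw_score = S, norm_score = Sn, p = p, p_adj = p_adj,
                    significant = p_adj < 0.05)
  class(out) <- c("ScoreResult", class(out))
  out
}

#' Cell-type association summary
#'
#' Per cell type: the proportion of significant cells (BH-adjusted p <
#' 0.05), and an association p-value from a one-sided binomial test of the
#' count of nominally significant cells (P_c < 0.05) against expectation
#' 0.05, BH-adjusted across the reported types.
#'
#' @param sr a \code{ScoreResult}.
#' @param cell_types per-cell labels aligned with \code{sr}.
#' @return data.frame (cell_type, n_cells, n_sig, prop_sig, n_nominal,
#'   assoc_p, assoc_p_adj).
#' @export
celltype_association <- function(sr, cell_types) {
  if (nrow(sr) != length(cell_types))
    stop("cell_types must align with the score result")
  types <- sort(unique(cell_types))
  rows <- lapply(types, function(ct) {
    i <- cell_types == ct
    n <- sum(i)
    nominal <- sum(sr$p[i] < 0.05)
    bp <- stats::binom.test(nominal, n, p = 0.05,
                            alternative = "greater")$p.value
    data.frame(cell_type = ct, n_cells = n, n_sig = sum(sr$significant[i]),
               prop_sig = mean(sr$significant[i]), n_nominal = nominal,
               assoc_p = bp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$assoc_p_adj <- stats::p.adjust(out$assoc_p, method = "BH")
  out
}
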