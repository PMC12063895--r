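#' Simulate an LD-blocked genotype panel
#'
#' Draws allele dosages for \code{n_ind} individuals at \code{m_snps} SNPs.
#' SNPs are organised into consecutive blocks of \code{block_size}; within a
#' block the latent haplotype Gaussians share an equicorrelation \code{rho},
#' between blocks they are independent. Each haplotype allele is obtained by
#' thresholding its latent Gaussian at \code{qnorm(maf)} (a Gaussian copula),
#' so the minor-allele frequency is controlled exactly in expectation and the
#' block LD structure is analytically known.
#'
#' @param n_ind number of individuals (>= 2).
#' @param m_snps number of SNPs (>= 1).
#' @param block_size SNPs per LD block.
#' @param rho latent within-block equicorrelation, in [0, 1); either a
#'   scalar or a vector recycled across blocks (heterogeneous LD gives the
#'   LD scores the spread that LD-score regression needs for a
#'   well-conditioned slope).
#' @param maf_range interval inside (0, 0.5] from which per-SNP MAFs are drawn
#'   uniformly.
#' @param seed integer seed; the draw is bit-reproducible given it.
#' @param chr chromosome label assigned to all SNPs (autosome 1..22).
#' @param spacing_bp base-pair spacing between consecutive SNPs.
#' @return A \code{GenotypePanel}: list with \code{genotypes} (individuals x
#'   SNPs dosage matrix in \{0,1,2\}), \code{variants} (snp_id, chr, pos, a1,
#'   a2, maf, info, block) and \code{individuals}.
#' @export
simulate_genotypes <- function(n_ind, m_snps, block_size = 10, rho = 0,
                               maf_range = c(0.05, 0.5), seed = 1,
                               chr = 1L, spacing_bp = 2000L) {
  if (n_ind < 2) stop("n_ind must be >= 2")
  if (m_snps < 1) stop("m_snps must be >= 1")
  if (block_size < 1) stop("block_size must be >= 1")
  if (any(rho < 0) || any(rho >= 1)) stop("rho must lie in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("invalid maf_range: must be an interval inside (0, 0.5]")
  if (!chr %in% 1:22) stop("chr must be an autosome 1..22")
  set.seed(as.integer(seed))

  maf <- stats::runif(m_snps, maf_range[1], maf_range[2])
  block <- rep(seq_len(ceiling(m_snps / block_size)), each = block_size)[seq_len(m_snps)]
  thr <- stats::qnorm(maf)
  rho_b <- rep_len(rho, max(block))
  rho_snp <- rho_b[block]

  draw_haplotype <- function() {
    e <- matrix(stats::rnorm(n_ind * m_snps), n_ind, m_snps)
    u <- matrix(stats::rnorm(n_ind * max(block)), n_ind, max(block))
    latent <- sweep(e, 2, sqrt(1 - rho_snp), `*`) +
      sweep(u[, block, drop = FALSE], 2, sqrt(rho_snp), `*`)
    # allele = 1 with probability maf_j
    sweep(latent, 2, thr, `<`) * 1L
  }
  geno <- draw_haplotype() + draw_haplotype()

  # guard against monomorphic columns at small n: redraw those columns as
  # independent Bernoulli haplotypes (breaks within-block LD for the rare
  # redrawn column only)
  mono <- which(apply(geno, 2, function(g) length(unique(g)) == 1L))
  for (j in mono) {
    for (try in 1:200) {
      g <- stats::rbinom(n_ind, 1, maf[j]) + stats::rbinom(n_ind, 1, maf[j])
      if (length(unique(g)) > 1L) { geno[, j] <- g; break }
    }
    if (length(unique(geno[, j])) == 1L)
      geno[1, j] <- if (geno[1, j] == 0) 1L else 0L
  }

  alleles <- c("A", "C", "G", "T")
  a1 <- sample(alleles, m_snps, replace = TRUE)
  a2 <- vapply(a1, function(a) sample(setdiff(alleles, a), 1), character(1))
  snp_id <- sprintf("snp%06d", seq_len(m_snps))
  ind_id <- sprintf("ind%05d", seq_len(n_ind))
  dimnames(geno) <- list(ind_id, snp_id)

  panel <- list(
    genotypes = geno,
    variants = data.frame(
      snp_id = snp_id, chr = as.integer(chr),
      pos = as.integer(seq_len(m_snps)) * as.integer(spacing_bp),
      a1 = a1, a2 = unname(a2), maf = maf, info = 1,
      block = block, stringsAsFactors = FALSE
    ),
    individuals = ind_id
  )
  class(panel) <- "GenotypePanel"
  panel
}

#' @export
print.GenotypePanel <- function(x, ...) {
  cat(sprintf("GenotypePanel: %d individuals x %d SNPs (chr %s)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              paste(unique(x$variants$chr), collapse = ",")))
  invisible(x)
}

#' Specify a heritable quantitative trait
#'
#' @param h2_true fraction of trait variance explained by the causal SNPs,
#'   in [0, 1].
#' @param n_causal number of causal SNPs (ignored when \code{causal_effects}
#'   is supplied).
#' @param causal_effects optional data.frame (snp_id, beta_true) pinning the
#'   causal architecture; betas are rescaled at simulation time so the genetic
#'   variance share equals \code{h2_true}.
#' @return A \code{TraitSpec} list.
#' @export
trait_spec <- function(h2_true, n_causal = 0L, causal_effects = NULL) {
  if (h2_true < 0 || h2_true > 1) stop("h2_true must lie in [0, 1]")
  if (is.null(causal_effects) && h2_true > 0 && n_causal == 0)
    stop("h2_true > 0 requires n_causal > 0 or explicit causal_effects")
  structure(list(h2_true = h2_true, n_causal = as.integer(n_causal),
                 causal_effects = causal_effects),
            class = "TraitSpec")
}

#' Simulate a quantitative trait on a genotype panel
#'
#' \code{y = X_std beta + e}, with betas rescaled so that the empirical
#' genetic variance share equals \code{h2_true}; the realized share is
#' recorded alongside the trait. Environmental noise is Gaussian.
#'
#' @param panel a \code{GenotypePanel}.
#' @param spec a \code{TraitSpec}.
#' @param seed integer seed.
#' @return list with \code{y} (one value per individual),
#'   \code{realized_share}, \code{causal_effects} (rescaled betas on the
#'   standardized-dosage scale) and \code{h2_true}.
#' @export
simulate_trait <- function(panel, spec, seed = 1) {
  stopifnot(inherits(panel, "GenotypePanel"), inherits(spec, "TraitSpec"))
  set.seed(as.integer(seed))
  n <- nrow(panel$genotypes)
  h2 <- spec$h2_true

  if (h2 == 0 && is.null(spec$causal_effects)) {
    y <- stats::rnorm(n)
    return(list(y = y, realized_share = 0,
                causal_effects = data.frame(snp_id = character(0),
                                            beta_true = numeric(0)),
                h2_true = 0))
  }

  ce <- spec$causal_effects
  if (is.null(ce)) {
    if (spec$n_causal > ncol(panel$genotypes))
      stop("n_causal exceeds the number of SNPs in the panel")
    idx <- sort(sample.int(ncol(panel$genotypes), spec$n_causal))
    ce <- data.frame(snp_id = panel$variants$snp_id[idx],
                     beta_true = stats::rnorm(spec$n_causal),
                     stringsAsFactors = FALSE)
  }
  j <- match(ce$snp_id, panel$variants$snp_id)
  if (anyNA(j)) stop("causal SNPs missing from the panel: ",
                     paste(ce$snp_id[is.na(j)], collapse = ", "))
  xs <- scale(panel$genotypes[, j, drop = FALSE])
  g <- drop(xs %*% ce$beta_true)
  vg <- stats::var(g)
  if (vg <= 0) stop("degenerate genetic component (all causal SNPs constant)")
  sc <- sqrt(h2 / vg)
  g <- g * sc
  ce$beta_true <- ce$beta_true * sc
  e <- if (h2 >= 1) rep(0, n) else stats::rnorm(n, sd = sqrt(1 - h2))
  y <- g + e
  list(y = y, realized_share = stats::var(g) / stats::var(y),
       causal_effects = ce, h2_true = h2)
}

#' Marginal GWAS summary statistics for one trait
#'
#' Per SNP, a simple linear regression of the trait on the allele dosage
#' (with intercept): beta, SE, z = beta/SE, sample size and a1 allele
#' frequency. Monomorphic SNPs have undefined SE and are flagged; downstream
#' QC removes them.
#'
#' @param panel a \code{GenotypePanel}.
#' @param y numeric trait vector (or the list returned by
#'   \code{\link{simulate_trait}}).
#' @param trait_id label carried through the pipeline.
#' @return A \code{SummaryStats} object (see \code{\link{sumstats}}).
#' @export
compute_summary_stats <- function(panel, y, trait_id = "trait") {
  stopifnot(inherits(panel, "GenotypePanel"))
  if (is.list(y)) y <- y$y
  X <- panel$genotypes
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal the number of individuals")
  xm <- colMeans(X)
  ym <- mean(y)
  sxx <- colSums(X^2) - n * xm^2
  sxy <- drop(crossprod(X, y)) - n * xm * ym
  syy <- sum(y^2) - n * ym^2
  beta <- sxy / sxx
  s2 <- pmax(syy - beta * sxy, 0) / (n - 2)
  se <- sqrt(s2 / sxx)
  # monomorphic SNPs have an undefined SE; flagged records are removed by QC
  flagged <- sxx <= 0 | !is.finite(beta)
  beta[flagged] <- NA_real_
  se[flagged] <- NA_real_
  rec <- data.frame(
    snp_id = panel$variants$snp_id, chr = panel$variants$chr,
    pos = panel$variants$pos, a1 = panel$variants$a1, a2 = panel$variants$a2,
    beta = beta, se = se, z = beta / se, n = n, frq = xm / 2,
    flagged = flagged, stringsAsFactors = FALSE
  )
  sumstats(rec, trait_id = trait_id)
}

#' Specify a synthetic single-cell population
#'
#' Negative-binomial counts (var = mu + mu^2/size) per gene and cell type.
#' Disease genes get their mean multiplied by \code{2^effect_log2} in the
#' designated target cell types; \code{effect_log2 = 0} reproduces the null
#' exactly. An optional \code{group_effect_log2} additionally upregulates the
#' disease genes in severe-group cells, giving the differential-expression
#' stage a known truth.
#'
#' @param genes character vector of gene ids.
#' @param base_means per-gene NB means (> 0), recycled if length 1.
#' @param cell_types labels.
#' @param n_cells_per_type counts, one per cell type.
#' @param disease_genes subset of \code{genes}.
#' @param effect_log2 log2 upregulation of disease genes in
#'   \code{target_types}.
#' @param target_types cell types receiving the disease-gene effect.
#' @param size NB size (dispersion) parameter; default 10, moderate
#'   overdispersion.
#' @param severe_frac fraction of cells per type labelled "severe" (the rest
#'   are "mild").
#' @param group_effect_log2 extra log2 upregulation of disease genes in
#'   severe cells.
#' @return A \code{CellPopSpec} list.
#' @export
cellpop_spec <- function(genes, base_means, cell_types, n_cells_per_type,
                         disease_genes = character(0), effect_log2 = 0,
                         target_types = character(0), size = 10,
                         severe_frac = 0.5, group_effect_log2 = 0) {
  base_means <- rep_len(base_means, length(genes))
  if (any(base_means <= 0)) stop("all NB means must be > 0")
  if (!all(disease_genes %in% genes))
    stop("disease_genes must be a subset of the gene universe")
  if (length(n_cells_per_type) != length(cell_types))
    stop("n_cells_per_type must align with cell_types")
  structure(list(genes = genes, base_means = base_means,
                 cell_types = cell_types,
                 n_cells_per_type = as.integer(n_cells_per_type),
                 disease_genes = disease_genes, effect_log2 = effect_log2,
                 target_types = target_types, size = size,
                 severe_frac = severe_frac,
                 group_effect_log2 = group_effect_log2),
            class = "CellPopSpec")
}

#' Simulate single-cell counts with cell-type labels
#'
#' @param spec a \code{CellPopSpec}.
#' @param seed integer seed.
#' @return A \code{\link{CellMatrix}} with raw NB counts and per-cell
#'   metadata (cell_id, cell_type, group).
#' @export
simulate_cells <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "CellPopSpec"))
  set.seed(as.integer(seed))
  keep <- spec$n_cells_per_type > 0
  types <- rep(spec$cell_types[keep], spec$n_cells_per_type[keep])
  n_cell <- length(types)
  if (n_cell == 0) stop("no cells requested")
  g <- length(spec$genes)
  dg <- spec$genes %in% spec$disease_genes

  group <- unlist(lapply(spec$n_cells_per_type[keep], function(k) {
    ns <- round(k * spec$severe_frac)
    sample(c(rep("severe", ns), rep("mild", k - ns)))
  }))

  counts <- matrix(0L, g, n_cell)
  for (ct in unique(types)) {
    sel <- which(types == ct)
    mu <- spec$base_means
    if (ct %in% spec$target_types && any(dg))
      mu[dg] <- mu[dg] * 2^spec$effect_log2
    sev <- sel[group[sel] == "severe"]
    mld <- setdiff(sel, sev)
    if (spec$group_effect_log2 != 0 && any(dg)) {
      mu_sev <- mu
      mu_sev[dg] <- mu_sev[dg] * 2^spec$group_effect_log2
    } else mu_sev <- mu
    if (length(mld))
      counts[, mld] <- stats::rnbinom(g * length(mld), mu = mu,
                                      size = spec$size)
    if (length(sev))
      counts[, sev] <- stats::rnbinom(g * length(sev), mu = mu_sev,
                                      size = spec$size)
  }
  cell_id <- sprintf("cell%06d", seq_len(n_cell))
  dimnames(counts) <- list(spec$genes, cell_id)
  cell_matrix(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
              data.frame(cell_id = cell_id, cell_type = types, group = group,
                         stringsAsFactors = FALSE))
}

#' Simulate per-individual pseudo-bulk expression with known cis effects
#'
#' expr = sum of w_true times standardized cis dosage + Gaussian noise.
#'
#' @param panel a \code{GenotypePanel}.
#' @param gene one-row gene record (gene_id, chr, start, end).
#' @param causal_weights data.frame (snp_id, w_true); all SNPs must lie in
#'   the gene's cis window.
#' @param noise_sd standard deviation of the additive noise.
#' @param seed integer seed.
#' @param cis_kb cis window half-width used to validate the causal SNPs.
#' @return list with \code{expr} (one value per individual) and
#'   \code{realized_cis_share}.
#' @export
simulate_pseudobulk_expression <- function(panel, gene, causal_weights,
                                           noise_sd, seed = 1, cis_kb = 500) {
  stopifnot(inherits(panel, "GenotypePanel"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  n <- nrow(panel$genotypes)
  v <- panel$variants
  lo <- gene$start - cis_kb * 1000
  hi <- gene$end + cis_kb * 1000
  j <- match(causal_weights$snp_id, v$snp_id)
  if (anyNA(j)) stop("causal SNPs missing from panel")
  incis <- v$chr[j] == gene$chr & v$pos[j] >= lo & v$pos[j] <= hi
  if (!all(incis)) stop("causal SNPs must lie in the gene's cis window")
  g <- if (all(causal_weights$w_true == 0)) rep(0, n) else
    drop(scale(panel$genotypes[, j, drop = FALSE]) %*% causal_weights$w_true)
  e <- stats::rnorm(n, sd = noise_sd)
  expr <- g + e
  vs <- stats::var(expr)
  list(expr = expr,
       realized_cis_share = if (vs > 0) stats::var(g) / vs else 0)
}
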