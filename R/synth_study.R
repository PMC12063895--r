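#' Generate a complete linked synthetic study
#'
#' Writes every input the pipeline consumes into \code{dir}, with known
#' ground truth: an LD-blocked genotype panel (PLINK bed/bim/fam); two
#' microbial-abundance traits with GWAS summary statistics -- the signal
#' trait's causal SNPs sit inside the cis blocks of designated signal genes,
#' the control trait is equally heritable but its causal SNPs sit in genes
#' that are neither upregulated in cells nor given cis-eQTL effects; a
#' single-cell count matrix in which the signal genes are upregulated in one
#' target cell type; per-individual pseudo-bulk expression for that cell
#' type with cis effects on the signal genes; a small GMT collection whose
#' first term is the signal gene set; a trait metadata table with taxonomy
#' strings; and \code{truth.json} recording the ground truth. The run
#' configuration (\code{run.yaml}) is also written.
#'
#' @param dir output directory.
#' @param seed master seed.
#' @param n_ind individuals in the panel.
#' @param n_blocks LD blocks of \code{block_size} SNPs (20 kb spacing).
#' @param block_size SNPs per block.
#' @param rho within-block latent correlation; the default cycles three
#'   levels across blocks so LD scores vary enough to identify the LDSC
#'   slope.
#' @param n_genes genes with coordinates (each covering one odd-numbered
#'   block, so gene windows never overlap).
#' @param n_signal signal genes (upregulated in the target type and carrying
#'   the signal trait's causal SNPs).
#' @param n_eqtl genes given a true cis-eQTL effect (>= n_signal).
#' @param cells_per_type cells per cell type.
#' @param h2_signal,h2_control trait heritabilities.
#' @param effect_log2 disease-gene upregulation in the target type.
#' @param cis_share variance share of the cis effect in pseudo-bulk
#'   expression.
#' @param B Monte-Carlo control draws used by the run configuration.
#' @return the \code{RunConfig} for the written study, invisibly; the
#'   ground truth is in \code{file.path(dir, "truth.json")}.
#' @export
simulate_study <- function(dir, seed = 1, n_ind = 800, n_blocks = 60,
                           block_size = 5, rho = c(0.1, 0.45, 0.8),
                           n_genes = 30,
                           n_signal = 6, n_eqtl = 6, cells_per_type = 300,
                           h2_signal = 0.5, h2_control = 0.3,
                           effect_log2 = 1, cis_share = 0.4, B = 300) {
  stopifnot(n_signal <= n_eqtl, n_eqtl <= n_genes, 2 * n_genes <= n_blocks)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- n_blocks * block_size
  spacing <- 20000L

  panel <- simulate_genotypes(n_ind, m, block_size = block_size, rho = rho,
                              maf_range = c(0.1, 0.5),
                              seed = derive_seed(seed, 1),
                              spacing_bp = spacing)
  write_plink(panel, file.path(dir, "panel"))

  # gene i covers odd block 2i-1; windows of neighbouring genes never touch
  v <- panel$variants
  gene_block <- 2 * seq_len(n_genes) - 1
  genes <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    idx <- which(v$block == gene_block[i])
    data.frame(gene_id = sprintf("g%03d", i), chr = 1L,
               start = v$pos[idx[1]] - 1000L,
               end = v$pos[idx[length(idx)]] + 1000L,
               stringsAsFactors = FALSE)
  }))
  write_tsv(genes, file.path(dir, "genes_coords.tsv"))

  # causal SNP of gene i = middle SNP of its block
  mid_snp <- vapply(gene_block, function(b) {
    idx <- which(v$block == b)
    v$snp_id[idx[ceiling(length(idx) / 2)]]
  }, character(1))

  # Mixed architecture: a genome-wide polygenic background (so LD-score
  # regression sees the infinitesimal model it assumes) plus concentrated
  # effects at the mid SNP of each focal gene (so the gene-level statistic
  # and TWAS have localized signal). 60% of the genetic variance is
  # polygenic, 40% concentrated.
  mixed_effects <- function(strong_snps, mix_seed, zero_snps = character(0)) {
    set.seed(mix_seed)
    beta <- stats::rnorm(m) * sqrt(0.6 / m)
    beta[v$snp_id %in% zero_snps] <- 0
    beta[match(strong_snps, v$snp_id)] <-
      beta[match(strong_snps, v$snp_id)] +
      sqrt(0.4 / length(strong_snps))
    data.frame(snp_id = v$snp_id, beta_true = beta, stringsAsFactors = FALSE)
  }
  # concentrated effects cover every SNP of a focal gene's block: spreading
  # them keeps the per-SNP chi2 moderate, so the handful of strong blocks
  # does not act as leverage outliers in the LD-score regression
  block_snps <- function(gene_idx)
    v$snp_id[v$block %in% gene_block[gene_idx]]
  # signal trait: concentrated SNPs inside signal genes g001..g{n_signal}
  sig_ce <- mixed_effects(block_snps(seq_len(n_signal)), derive_seed(seed, 20))
  t_sig <- simulate_trait(panel, trait_spec(h2_signal,
                                            causal_effects = sig_ce),
                          seed = derive_seed(seed, 2))
  # control trait: equally gated, but its concentrated SNPs sit in the last
  # n_signal genes, which have no cis-eQTL effect and no upregulation in
  # the cells. Its polygenic background is zeroed inside the cis windows of
  # the expression-modeled genes: a negative-control trait must have no
  # genetic effect acting through the modeled genes, or its TWAS "false
  # positives" would be true mediation.
  ctl_genes <- seq(n_genes - n_signal + 1, n_genes)
  modeled <- seq_len(min(n_eqtl + 2, n_genes))
  cis_zero <- v$snp_id[vapply(seq_len(m), function(j) {
    any(v$pos[j] >= genes$start[modeled] - 50000 &
          v$pos[j] <= genes$end[modeled] + 50000)
  }, logical(1))]
  ctl_ce <- mixed_effects(block_snps(ctl_genes), derive_seed(seed, 21),
                          zero_snps = cis_zero)
  t_ctl <- simulate_trait(panel, trait_spec(h2_control,
                                            causal_effects = ctl_ce),
                          seed = derive_seed(seed, 3))
  ss_sig <- compute_summary_stats(panel, t_sig, trait_id = "trait_signal")
  ss_ctl <- compute_summary_stats(panel, t_ctl, trait_id = "trait_control")
  write_sumstats(ss_sig, file.path(dir, "sumstats_signal.tsv"))
  write_sumstats(ss_ctl, file.path(dir, "sumstats_control.tsv"))

  traits <- data.frame(
    trait_id = c("trait_signal", "trait_control"),
    sumstats = file.path(dir, c("sumstats_signal.tsv",
                                "sumstats_control.tsv")),
    site = c("tongue", "saliva"),
    taxonomy = c("k__Bacteria; p__Firmicutes; c__Clostridia; o__Lachnospirales; f__Lachnospiraceae; g__Oribacterium; s__synthetic_mgs_0001",
                 "k__Bacteria; p__Bacteroidota; c__Bacteroidia; o__Bacteroidales; f__Bacteroidaceae; g__Prevotella; s__synthetic_mgs_0002"),
    stringsAsFactors = FALSE)
  write_tsv(traits, file.path(dir, "traits.tsv"))

  # single-cell counts: universe of 200 genes; the first n_genes ids match
  # the coordinate table, the rest are filler for control-gene matching
  n_universe <- max(200, n_genes)
  universe <- c(genes$gene_id,
                sprintf("f%03d", seq_len(n_universe - n_genes)))
  set.seed(derive_seed(seed, 4))
  base_means <- exp(stats::runif(n_universe, log(0.3), log(4)))
  types <- c("CD16_Mono", "CD14_Mono", "NK", "B")
  signal_genes <- genes$gene_id[seq_len(n_signal)]
  spec <- cellpop_spec(universe, base_means, types,
                       rep(cells_per_type, length(types)),
                       disease_genes = signal_genes,
                       effect_log2 = effect_log2,
                       target_types = "CD16_Mono",
                       severe_frac = 0.5, group_effect_log2 = 0.5)
  cm <- simulate_cells(spec, seed = derive_seed(seed, 5))
  write_mtx_dir(cm, file.path(dir, "cells"))

  # pseudo-bulk expression (target cell type): cis effect on the first
  # n_eqtl genes, pure noise on two extra genes to exercise model rejection
  noise_sd <- sqrt(1 / cis_share - 1)
  expr_genes <- genes$gene_id[seq_len(min(n_eqtl + 2, n_genes))]
  expr <- t(vapply(seq_along(expr_genes), function(i) {
    g <- genes[genes$gene_id == expr_genes[i], , drop = FALSE]
    if (i <= n_eqtl) {
      cw <- data.frame(snp_id = mid_snp[i], w_true = 1)
      simulate_pseudobulk_expression(panel, g, cw, noise_sd = noise_sd,
                                     seed = derive_seed(seed, 10 + i),
                                     cis_kb = 50)$expr
    } else {
      set.seed(derive_seed(seed, 10 + i))
      stats::rnorm(n_ind)
    }
  }, numeric(n_ind)))
  rownames(expr) <- expr_genes
  colnames(expr) <- panel$individuals
  utils::write.table(cbind(gene_id = rownames(expr), as.data.frame(expr)),
                     file.path(dir, "expression_CD16_Mono.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # gene sets: the signal set plus random terms
  set.seed(derive_seed(seed, 6))
  sets <- c(list(signal_set = signal_genes),
            stats::setNames(lapply(1:5, function(i)
              sample(universe, 15)), sprintf("random_set_%d", 1:5)))
  write_gmt(sets, file.path(dir, "sets.gmt"))

  truth <- list(seed = seed,
                signal_trait = "trait_signal",
                control_trait = "trait_control",
                h2_true = list(trait_signal = h2_signal,
                               trait_control = h2_control),
                signal_genes = signal_genes,
                eqtl_genes = genes$gene_id[seq_len(n_eqtl)],
                causal_snps = list(
                  trait_signal = mid_snp[seq_len(n_signal)],
                  trait_control = mid_snp[ctl_genes]),
                target_cell_type = "CD16_Mono",
                effect_log2 = effect_log2, cis_share = cis_share,
                realized_share = list(trait_signal = t_sig$realized_share,
                                      trait_control = t_ctl$realized_share))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg <- run_config(
    panel_prefix = file.path(dir, "panel"),
    traits = file.path(dir, "traits.tsv"),
    gene_table = file.path(dir, "genes_coords.tsv"),
    cells_dir = file.path(dir, "cells"),
    expression = list(CD16_Mono = file.path(dir, "expression_CD16_Mono.tsv")),
    gmt = file.path(dir, "sets.gmt"),
    out_dir = file.path(dir, "out"),
    seed = seed, top_k = n_signal, B = B, cis_kb = 50,
    window_kb = 10, ld_window_bp = 200000,
    do_qc_cells = FALSE, folds = 3, inner_nfolds = 3)
  yaml::write_yaml(unclass(cfg), file.path(dir, "run.yaml"))
  invisible(cfg)
}
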