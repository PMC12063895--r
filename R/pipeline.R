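# stage-local seeds derived from the master seed (kept below 2^31)
derive_seed <- function(master, idx) {
  as.integer((as.numeric(master) * 1000003 + 97 * idx) %% 2147483647L)
}

#' Assemble a run configuration
#'
#' @param path optional YAML file; fields given directly override it.
#' @param ... configuration fields (see Details).
#' @details Fields: \code{panel_prefix}, \code{traits} (data.frame or TSV
#'   path: trait_id, sumstats, site, taxonomy), \code{gene_table},
#'   \code{cells_dir}, \code{expression} (named list cell_type -> TSV of
#'   genes x individuals), \code{gmt}, \code{out_dir}, \code{seed}, and
#'   thresholds \code{h2_gate} (0.1), \code{top_k} (1000), \code{B} (1000),
#'   \code{fc_threshold} (0.25), \code{alpha} (0.05), \code{cis_kb} (500),
#'   \code{window_kb} (10), \code{ld_window_bp} (1e6), \code{score_group}
#'   ("severe"), stage toggles \code{do_qc_cells}, \code{do_geneassoc},
#'   \code{do_scdrs}, \code{do_twas}, \code{do_deg}, \code{do_enrich}.
#' @return a \code{RunConfig} list with defaults filled in.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  dots <- list(...)
  cfg[names(dots)] <- dots
  defaults <- list(h2_gate = 0.1, top_k = 1000, B = 1000,
                   fc_threshold = 0.25, alpha = 0.05, cis_kb = 500,
                   window_kb = 10, ld_window_bp = 1e6,
                   score_group = "severe", seed = 1,
                   do_qc_cells = TRUE, do_geneassoc = TRUE, do_scdrs = TRUE,
                   do_twas = TRUE, do_deg = TRUE, do_enrich = TRUE,
                   qc_min_genes = 200, qc_max_umi = 20000,
                   qc_max_mito_frac = 0.15, qc_min_cells_per_gene = 3,
                   h2_gate_p = 0.05, folds = 5, inner_nfolds = 5)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  structure(cfg, class = "RunConfig")
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full inference chain
#'
#' Stages, in order: summary-statistic QC; LD-score heritability with the h2
#' gate; gene-level association and disease-gene-set construction; per-cell
#' disease scoring with cell-type association; cis-eQTL training and TWAS;
#' differential expression; over-representation analysis; phylum tabulation.
#' Every stage's input/output row counts are appended to \code{run.log};
#' identical config and seed give byte-identical outputs.
#'
#' @param config a \code{RunConfig} (or path to a YAML config).
#' @return the output directory, invisibly; TSV tables are written there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- run_config(path = config)
  stopifnot(inherits(config, "RunConfig"))
  out <- config$out_dir
  if (is.null(out)) stop("config must set out_dir")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  logf <- function(...) log_lines <<- c(log_lines, sprintf(...))
  logf("florascore run, master seed %d", as.integer(config$seed))
  for (nm in c("h2_gate", "top_k", "B", "fc_threshold", "alpha", "cis_kb",
               "window_kb", "ld_window_bp", "score_group"))
    logf("param %s = %s", nm, paste(config[[nm]], collapse = ","))

  traits <- config$traits
  if (is.character(traits))
    traits <- utils::read.table(traits, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  panel <- read_plink(config$panel_prefix)
  logf("panel: %d individuals x %d SNPs", nrow(panel$genotypes),
       ncol(panel$genotypes))

  ## stage 1-2: sumstats QC + heritability gate -----------------------------
  ld <- compute_ld_scores(panel, window_bp = config$ld_window_bp)
  qc_rows <- list(); h2_rows <- list(); ss_list <- list()
  for (i in seq_len(nrow(traits))) {
    tid <- traits$trait_id[i]
    ss <- read_sumstats(traits$sumstats[i], trait_id = tid)
    qr <- qc_filter(ss)
    qc_rows[[tid]] <- cbind(trait_id = tid, qr$report)
    logf("sumstats %s: %d -> %d SNPs after QC", tid, qr$n_in, qr$n_out)
    est <- estimate_h2_ldsc(qr$ss, ld, M = nrow(ld))
    gate <- heritability_gate(est, threshold = config$h2_gate)
    h2_rows[[tid]] <- data.frame(trait_id = tid, h2 = est$h2,
                                 intercept = est$intercept,
                                 se_h2 = est$se_h2, n_snps = est$n_snps,
                                 passed_gate = gate)
    if (gate) ss_list[[tid]] <- qr$ss
    logf("h2 %s: %.4f (gate %s)", tid, est$h2, gate)
  }
  write_tsv(do.call(rbind, qc_rows), file.path(out, "qc_report.tsv"))
  write_tsv(do.call(rbind, h2_rows), file.path(out, "h2.tsv"))
  gated <- names(ss_list)
  if (!length(gated)) {
    logf("no trait passed the h2 gate; stopping after sumstats stage")
    writeLines(log_lines, file.path(out, "run.log"))
    return(invisible(out))
  }

  ## stage 3: gene-level association ----------------------------------------
  genesets <- list()
  if (isTRUE(config$do_geneassoc)) {
    genes <- read_gene_table(config$gene_table)
    gr_rows <- list(); gs_rows <- list()
    for (tid in gated) {
      gr <- gene_association(ss_list[[tid]], genes, panel,
                             window_kb = config$window_kb)
      gr_rows[[tid]] <- cbind(trait_id = tid, gr)
      gs <- build_disease_gene_set(gr, top_k = config$top_k)
      genesets[[tid]] <- gs
      gs_rows[[tid]] <- data.frame(trait_id = tid, gene_id = gs$genes,
                                   weight = as.numeric(gs$weights))
      logf("geneassoc %s: %d genes tested, gene set size %d", tid,
           nrow(gr), gs$k)
    }
    write_tsv(do.call(rbind, gr_rows), file.path(out, "gene_results.tsv"))
    write_tsv(do.call(rbind, gs_rows), file.path(out, "geneset.tsv"))
  }

  ## stage 4: per-cell scoring ----------------------------------------------
  assoc_all <- NULL
  cm <- NULL
  if (isTRUE(config$do_scdrs) || isTRUE(config$do_deg)) {
    cm <- read_mtx_dir(config$cells_dir)
    logf("cells: %d genes x %d cells read", nrow(cm$counts), ncol(cm$counts))
    if (isTRUE(config$do_qc_cells)) {
      qc <- qc_cells(cm, min_genes = config$qc_min_genes,
                     max_umi = config$qc_max_umi,
                     max_mito_frac = config$qc_max_mito_frac,
                     min_cells_per_gene = config$qc_min_cells_per_gene)
      cm <- qc$cm
      for (k in seq_len(nrow(qc$report)))
        logf("cell QC rule %s removed %d", qc$report$rule[k],
             qc$report$removed[k])
    }
    if (!is.null(config$drop_types) && length(config$drop_types)) {
      ex <- exclude_subtypes(cm, config$drop_types)
      cm <- ex$cm
      logf("excluded subtypes %s: %d cells removed",
           paste(config$drop_types, collapse = ","), ex$n_removed)
    }
    cm <- normalize_expression(cm)
  }
  if (isTRUE(config$do_scdrs) && length(genesets)) {
    score_sel <- if (identical(config$score_group, "all"))
      rep(TRUE, n_cell(cm)) else cm$cells$group == config$score_group
    cms <- subset_cells(cm, score_sel)
    noise <- estimate_tech_noise(cms$norm)
    score_rows <- list(); assoc_rows <- list()
    for (ti in seq_along(gated)) {
      tid <- gated[ti]
      S <- raw_disease_score(cms$norm, genesets[[tid]], noise)
      ctrl <- sample_control_scores(cms$norm, genesets[[tid]], noise,
                                    B = config$B,
                                    seed = derive_seed(config$seed, 40 + ti))
      sr <- cell_pvalues(S, ctrl)
      score_rows[[tid]] <- data.frame(trait_id = tid,
                                      cell_id = cms$cells$cell_id,
                                      cell_type = cms$cells$cell_type, sr)
      a <- celltype_association(sr, cms$cells$cell_type)
      assoc_rows[[tid]] <- cbind(trait_id = tid, a)
      logf("scdrs %s: %d cells scored, %d significant", tid, nrow(sr),
           sum(sr$significant))
    }
    assoc_all <- do.call(rbind, assoc_rows)
    # BH across (cell type x trait) pairs
    assoc_all$assoc_p_adj <- stats::p.adjust(assoc_all$assoc_p, method = "BH")
    write_tsv(do.call(rbind, score_rows), file.path(out, "scdrs_scores.tsv"))
    write_tsv(assoc_all, file.path(out, "celltype_assoc.tsv"))
  }

  ## stage 5: cis-eQTL training + TWAS --------------------------------------
  twas_all <- NULL
  if (isTRUE(config$do_twas) && !is.null(config$expression)) {
    genes <- read_gene_table(config$gene_table)
    qcp <- genotype_qc_eqtl(panel)
    logf("eQTL genotype QC removed %d SNPs", sum(qcp$report$removed))
    twas_rows <- list()
    for (ct in names(config$expression)) {
      em <- as.matrix(utils::read.table(config$expression[[ct]],
                                        header = TRUE, sep = "\t",
                                        row.names = 1, check.names = FALSE))
      n_model <- 0L
      for (g in intersect(rownames(em), genes$gene_id)) {
        grec <- genes[genes$gene_id == g, , drop = FALSE]
        sub <- extract_cis_snps(qcp$panel, grec, cis_kb = config$cis_kb)
        if (is.null(sub)) next
        model <- suppressMessages(
          fit_weights(sub, em[g, ], folds = config$folds,
                      seed = derive_seed(config$seed, 60 + n_model),
                      gene_id = g, cell_type = ct,
                      h2_gate_p = config$h2_gate_p,
                      inner_nfolds = config$inner_nfolds))
        if (is.null(model)) next
        n_model <- n_model + 1L
        j <- match(model$snp_ids, qcp$panel$variants$snp_id)
        R_ref <- if (length(j) == 1) matrix(1, 1, 1) else
          stats::cor(qcp$panel$genotypes[, j, drop = FALSE])
        for (tid in gated)
          twas_rows[[paste(g, ct, tid)]] <-
            cbind(twas_assoc(model, ss_list[[tid]], R_ref),
                  best_method = model$best_method,
                  cv_r2 = max(model$cv_r2), cis_h2 = model$cis_h2)
      }
      logf("twas %s: %d models trained", ct, n_model)
    }
    if (length(twas_rows)) {
      twas_all <- adjust_results(do.call(rbind, twas_rows))
      rownames(twas_all) <- NULL
      write_tsv(twas_all, file.path(out, "twas.tsv"))
      logf("twas: %d tests, %d nominal, %d study-wide", nrow(twas_all),
           sum(twas_all$nominal_sig), sum(twas_all$study_sig))
    }
  }

  ## stage 6: differential expression ---------------------------------------
  deg_all <- NULL
  if (isTRUE(config$do_deg) && !is.null(cm)) {
    deg_rows <- list()
    for (ct in sort(unique(cm$cells$cell_type))) {
      grp <- cm$cells$group[cm$cells$cell_type == ct]
      if (sum(grp == "severe") < 3 || sum(grp == "mild") < 3) next
      deg_rows[[ct]] <- wilcoxon_deg(cm, ct,
                                     fc_threshold = config$fc_threshold,
                                     alpha = config$alpha)
      logf("deg %s: %d genes, %d DEGs", ct, nrow(deg_rows[[ct]]),
           sum(deg_rows[[ct]]$is_deg))
    }
    if (length(deg_rows)) {
      deg_all <- do.call(rbind, deg_rows)
      rownames(deg_all) <- NULL
      write_tsv(deg_all, file.path(out, "deg.tsv"))
    }
  }

  ## stage 7: over-representation -------------------------------------------
  if (isTRUE(config$do_enrich) && !is.null(config$gmt) &&
      !is.null(twas_all) && !is.null(deg_all)) {
    sets <- read_gmt(config$gmt)
    enr_rows <- list()
    for (tid in gated) for (ct in unique(twas_all$cell_type)) {
      nom <- twas_all$gene_id[twas_all$trait_id == tid &
                                twas_all$cell_type == ct &
                                twas_all$nominal_sig]
      degs <- deg_all$gene_id[deg_all$cell_type == ct & deg_all$is_deg]
      query <- intersect(nom, degs)
      if (!length(query)) next
      universe <- deg_all$gene_id[deg_all$cell_type == ct]
      er <- ora_enrichment(query, sets, universe)
      if (nrow(er))
        enr_rows[[paste(tid, ct)]] <- cbind(trait_id = tid, cell_type = ct, er)
    }
    if (length(enr_rows)) {
      enr <- do.call(rbind, enr_rows)
      rownames(enr) <- NULL
      write_tsv(enr, file.path(out, "enrich.tsv"))
      logf("enrich: %d records", nrow(enr))
    } else logf("enrich: no nonempty query")
  }

  ## stage 8: phylum tabulation ---------------------------------------------
  if (!is.null(assoc_all) && all(c("taxonomy", "site") %in% names(traits))) {
    sig_by_trait <- tapply(assoc_all$assoc_p_adj, assoc_all$trait_id, min)
    tt <- traits[traits$trait_id %in% gated, , drop = FALSE]
    tt$significant <- sig_by_trait[tt$trait_id] < config$alpha
    tab <- tabulate_phyla(tt)
    write_tsv(tab, file.path(out, "phylum_table.tsv"))
    logf("phyla: %d rows", nrow(tab))
  }

  writeLines(log_lines, file.path(out, "run.log"))
  invisible(out)
}

#' Tabulate traits by phylum and sampling site
#'
#' Parses "k__...; p__...;" taxonomy strings, counts traits per phylum split
#' by site (saliva/tongue) and the number of significant traits per phylum.
#' Percentages are derived from the counts on output (row-wise shares of the
#' phylum total), never stored independently. Unparseable taxonomies count
#' under "Others" with a warning.
#'
#' @param traits data.frame with columns taxonomy, site and logical
#'   significant (one row per trait).
#' @param sig_alpha kept for interface compatibility; the significant flag
#'   is expected to be precomputed at this level.
#' @return data.frame (phylum, total, saliva, tongue, n_significant,
#'   pct_saliva, pct_tongue, pct_sig), ordered by total descending with
#'   "Others" last.
#' @export
tabulate_phyla <- function(traits, sig_alpha = 0.05) {
  stopifnot(all(c("taxonomy", "site") %in% names(traits)))
  if (!"significant" %in% names(traits)) traits$significant <- FALSE
  parse_phylum <- function(s) {
    f <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    hit <- grep("^p__", f, value = TRUE)
    if (!length(hit) || !nzchar(sub("^p__", "", hit[1]))) return(NA_character_)
    sub("^p__", "", hit[1])
  }
  ph <- vapply(as.character(traits$taxonomy), parse_phylum, character(1),
               USE.NAMES = FALSE)
  if (anyNA(ph)) {
    warning(sum(is.na(ph)), " trait(s) with unparseable taxonomy counted under 'Others'")
    ph[is.na(ph)] <- "Others"
  }
  site <- tolower(as.character(traits$site))
  rows <- lapply(unique(ph), function(p) {
    i <- ph == p
    data.frame(phylum = p, total = sum(i),
               saliva = sum(i & site == "saliva"),
               tongue = sum(i & site == "tongue"),
               n_significant = sum(i & traits$significant),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$phylum == "Others", -out$total, out$phylum), ,
             drop = FALSE]
  out$pct_saliva <- round(100 * out$saliva / out$total, 2)
  out$pct_tongue <- round(100 * out$tongue / out$total, 2)
  out$pct_sig <- round(100 * out$n_significant / out$total, 2)
  rownames(out) <- NULL
  out
}
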