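#' Wilcoxon differential expression, severe vs mild, within one cell type
#'
#' Per gene, a two-sided Wilcoxon rank-sum test on normalized expression
#' between severe- and mild-group cells of the given type
#' (\code{stats::wilcox.test}: exact for small untied samples, tie-corrected
#' normal approximation otherwise). log2 fold change is computed on de-logged
#' normalized means: log2((mean(expm1 severe) + eps) / (mean(expm1 mild) +
#' eps)) with eps = 1e-9. BH adjustment is across genes within the cell
#' type; a gene is a DEG iff p_adj < alpha and |log2fc| > fc_threshold.
#'
#' @param cm a normalized \code{CellMatrix} whose metadata carries
#'   \code{group} in \{mild, severe\}.
#' @param cell_type the cell type to test.
#' @param fc_threshold |log2FC| threshold for the DEG flag.
#' @param alpha BH-adjusted significance level for the DEG flag.
#' @param min_cells minimum cells required per group.
#' @return data.frame of \code{DegRecord} rows: gene_id, cell_type, log2fc,
#'   p, p_adj, is_deg.
#' @export
wilcoxon_deg <- function(cm, cell_type, fc_threshold = 0.25, alpha = 0.05,
                         min_cells = 3) {
  stopifnot(inherits(cm, "CellMatrix"))
  if (is.null(cm$norm)) stop("run normalize_expression first")
  sel <- cm$cells$cell_type == cell_type
  grp <- cm$cells$group[sel]
  for (g in c("severe", "mild"))
    if (sum(grp == g) < min_cells)
      stop("group '", g, "' has fewer than ", min_cells,
           " cells of type ", cell_type)
  X <- as.matrix(cm$norm[, sel, drop = FALSE])
  sev <- grp == "severe"
  eps <- 1e-9
  mu_s <- rowMeans(expm1(X[, sev, drop = FALSE]))
  mu_m <- rowMeans(expm1(X[, !sev, drop = FALSE]))
  log2fc <- log2((mu_s + eps) / (mu_m + eps))
  p <- vapply(seq_len(nrow(X)), function(i) {
    xs <- X[i, sev]; xm <- X[i, !sev]
    if (all(xs == xs[1]) && all(xm == xm[1]) && xs[1] == xm[1]) return(1)
    suppressWarnings(stats::wilcox.test(xs, xm)$p.value)
  }, numeric(1))
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = rownames(X), cell_type = cell_type, log2fc = log2fc,
             p = p, p_adj = p_adj,
             is_deg = p_adj < alpha & abs(log2fc) > fc_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric over-representation analysis
#'
#' Each term is intersected with the universe; the p-value is the exact
#' hypergeometric upper tail for an overlap at least as large as observed;
#' enrichment_ratio = overlap / query_size; terms with zero overlap are
#' dropped; BH across the tested terms.
#'
#' @param query character vector of genes (must lie in \code{universe}).
#' @param genesets named list of gene sets (e.g. from
#'   \code{\link{read_gmt}}).
#' @param universe background gene list.
#' @return data.frame of \code{EnrichRecord} rows: term_id, overlap,
#'   query_size, term_size, universe_size, enrichment_ratio, p, fdr.
#' @export
ora_enrichment <- function(query, genesets, universe) {
  query <- unique(query)
  if (!length(query)) stop("query gene list is empty")
  universe <- unique(universe)
  out <- setdiff(query, universe)
  if (length(out))
    stop("query genes outside the universe: ",
         paste(utils::head(out, 5), collapse = ", "))
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(genesets), function(tid) {
    term <- intersect(unique(genesets[[tid]]), universe)
    m <- length(term)
    k <- length(intersect(query, term))
    if (k == 0 || m == 0) return(NULL)
    p <- stats::phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    data.frame(term_id = tid, overlap = k, query_size = q, term_size = m,
               universe_size = N, enrichment_ratio = k / q, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term_id = character(0), overlap = integer(0),
                      query_size = integer(0), term_size = integer(0),
                      universe_size = integer(0),
                      enrichment_ratio = numeric(0), p = numeric(0),
                      fdr = numeric(0)))
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p), , drop = FALSE]
}
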