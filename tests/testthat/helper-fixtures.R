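# Build a GenotypePanel from a bare dosage matrix (hand fixtures).
make_panel <- function(geno, chr = 1L, pos = NULL, a1 = NULL, a2 = NULL,
                       info = 1) {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(a1)) a1 <- rep("A", m)
  if (is.null(a2)) a2 <- rep("G", m)
  snp_id <- if (is.null(colnames(geno))) sprintf("s%03d", seq_len(m)) else colnames(geno)
  ind <- if (is.null(rownames(geno))) sprintf("i%03d", seq_len(nrow(geno))) else rownames(geno)
  dimnames(geno) <- list(ind, snp_id)
  frq <- colMeans(geno) / 2
  structure(list(genotypes = geno,
                 variants = data.frame(snp_id = snp_id, chr = rep(chr, m),
                                       pos = pos, a1 = a1, a2 = a2,
                                       maf = pmin(frq, 1 - frq),
                                       info = rep(info, length.out = m),
                                       stringsAsFactors = FALSE),
                 individuals = ind),
            class = "GenotypePanel")
}

# Build a SummaryStats from minimal pieces.
make_ss <- function(snp_id, z, chr = 1L, pos = seq_along(snp_id) * 1000L,
                    a1 = "A", a2 = "G", n = 1000L, frq = 0.3,
                    trait_id = "t") {
  m <- length(snp_id)
  sumstats(data.frame(snp_id = snp_id, chr = rep(chr, length.out = m),
                      pos = pos, a1 = rep(a1, length.out = m),
                      a2 = rep(a2, length.out = m), beta = z, se = 1, z = z,
                      n = rep(n, length.out = m),
                      frq = rep(frq, length.out = m),
                      stringsAsFactors = FALSE),
           trait_id = trait_id)
}

# CellMatrix from a dense genes x cells matrix.
make_cm <- function(mat, cell_type = NULL, group = NULL) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  nc <- ncol(mat)
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("c%03d", seq_len(nc))
  if (is.null(cell_type)) cell_type <- rep("T", nc)
  if (is.null(group)) group <- rep("severe", nc)
  cell_matrix(Matrix::Matrix(mat, sparse = TRUE),
              data.frame(cell_id = colnames(mat), cell_type = cell_type,
                         group = group, stringsAsFactors = FALSE))
}

# Label-only CellMatrix (1 zero-count gene) from a cell-type count table,
# for subtype merge/exclusion arithmetic at scale.
make_label_cells <- function(types, counts) {
  n <- sum(counts)
  cell_type <- rep(types, counts)
  counts_mat <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                     x = numeric(0), dims = c(1, n))
  rownames(counts_mat) <- "dummy"
  colnames(counts_mat) <- sprintf("c%07d", seq_len(n))
  cell_matrix(counts_mat,
              data.frame(cell_id = colnames(counts_mat),
                         cell_type = cell_type, group = "severe",
                         stringsAsFactors = FALSE))
}

# A hand-made DiseaseGeneSet.
make_gs <- function(genes, weights) {
  structure(list(genes = genes,
                 weights = stats::setNames(weights, genes),
                 k = length(genes)),
            class = "DiseaseGeneSet")
}

# A hand-made CisModel.
make_cis_model <- function(snp_ids, weights, a1 = "A", a2 = "G",
                           gene_id = "g1", cell_type = "T",
                           method = "top1") {
  w <- list(); w[[method]] <- weights
  structure(list(gene_id = gene_id, cell_type = cell_type,
                 snp_ids = snp_ids,
                 a1 = rep(a1, length.out = length(snp_ids)),
                 a2 = rep(a2, length.out = length(snp_ids)),
                 weights = w, cv_r2 = stats::setNames(0.5, method),
                 best_method = method, cis_h2 = 0.3, cis_h2_p = 0.01),
            class = "CisModel")
}
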