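test_that("cell QC removes cells and genes by the stated rules in order", {
  # 100 cells over 300 genes: 93 clean, 3 low-complexity, 2 high-UMI,
  # 2 high mitochondrial fraction; plus one gene seen in only 2 cells
  ng <- 300
  genes <- c(sprintf("MT-%d", 1:5), sprintf("g%03d", 1:(ng - 5)))
  mat <- matrix(0, ng, 100, dimnames = list(genes, sprintf("c%03d", 1:100)))
  mat[6:255, 1:93] <- 1                       # clean: 250 genes, UMI 250
  mat[6:155, 94:96] <- 1                      # 150 genes expressed: removed
  mat[6:255, 97:98] <- 1; mat[6, 97:98] <- 19752   # UMI = 20000: removed
  mat[6:255, 99:100] <- 1
  mat[1, 99:100] <- 45                        # mito 45/294 > 0.15: removed
  rare <- "g250"
  mat[rare, ] <- 0; mat[rare, 1:2] <- 1       # expressed in 2 cells only
  cm <- make_cm(mat)
  qc <- qc_cells(cm, min_genes = 200, max_umi = 20000, max_mito_frac = 0.15,
                 min_cells_per_gene = 3)
  expect_equal(n_cell(qc$cm), 93)
  expect_equal(qc$report$removed, c(3L, 2L, 2L, 51L))
  expect_false(rare %in% qc$cm$genes)

  # boundary: total UMI exactly at the ceiling is removed (rule is >=)
  expect_equal(sum(Matrix::colSums(cm$counts) == 20000), 2)
  expect_error(qc_cells(cm, min_genes = 1000), "no cells remain")
})

test_that("subtype exclusion and merging reproduce label arithmetic", {
  counts <- utils::read.delim(
    system.file("extdata", "ili_celltype_counts.tsv", package = "florascore"))
  cm <- make_label_cells(counts$cell_type, counts$count)
  expect_equal(n_cell(cm), 51243)
  ex <- exclude_subtypes(cm, c("PLT", "RBC"))
  expect_equal(ex$n_removed, 4465)
  expect_equal(n_cell(ex$cm), 51243 - 4465)

  # empty drop set is the identity
  ex0 <- exclude_subtypes(cm, character(0))
  expect_equal(n_cell(ex0$cm), n_cell(cm))
  expect_error(exclude_subtypes(cm, "NotAType"), "valid labels")
  expect_error(exclude_subtypes(cm, unique(cm$cells$cell_type)),
               "every cell")

  # identity mapping leaves per-type counts unchanged
  map_id <- data.frame(source = counts$cell_type, target = counts$cell_type)
  cmi <- merge_subtypes(cm, map_id)
  expect_equal(as.vector(table(cmi$cells$cell_type)[counts$cell_type]),
               counts$count)
  expect_error(merge_subtypes(cm, map_id[-1, ]), "unmapped")
})

test_that("normalization is log1p counts-per-10k, exactly", {
  mat <- matrix(c(0, 1, 4,
                  2, 0, 1,
                  3, 5, 0), 3, 3, byrow = TRUE)
  cm <- normalize_expression(make_cm(mat))
  tot <- colSums(mat)
  expected <- log1p(sweep(mat, 2, 1e4 / tot, `*`))
  expect_equal(unname(as.matrix(cm$norm)), expected, tolerance = 1e-12)
  # zero count stays zero; a cell expressing one gene maps to log(1 + 1e4)
  expect_equal(as.matrix(cm$norm)[1, 1], 0)
  single <- normalize_expression(make_cm(matrix(c(7, 0), 2, 1)))
  expect_equal(as.matrix(single$norm)[1, 1], log(1 + 1e4), tolerance = 1e-12)

  expect_error(normalize_expression(make_cm(matrix(0, 2, 2))), "zero-total")
})

test_that("technical-noise sigmas follow bin-median variances with a floor", {
  # all genes identically distributed: a single sigma
  set.seed(3)
  X <- matrix(rpois(50 * 200, 2), 50, 200,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  tn <- estimate_tech_noise(Matrix::Matrix(log1p(X), sparse = TRUE))
  # identical means may split ranks only by sampling noise; all sigmas close
  expect_lt(diff(range(tn$sigma_tech)) / mean(tn$sigma_tech), 0.5)

  # constant genes: variance 0 is floored at 1e-4, sigma = 1e-2
  Xc <- matrix(1, 10, 20, dimnames = list(sprintf("g%02d", 1:10), NULL))
  tnc <- estimate_tech_noise(Matrix::Matrix(Xc, sparse = TRUE))
  expect_equal(unname(tnc$sigma_tech), rep(0.01, 10))

  # two constructed bins with variances 1 and 4 give sigma 1 and 2
  lo <- matrix(rep(c(0, 2), 50), 10, 100, byrow = TRUE)   # mean 1, var ~1
  hi <- matrix(rep(c(0, 4), 50), 10, 100, byrow = TRUE)   # mean 2, var ~4
  Xb <- rbind(lo, hi)
  rownames(Xb) <- sprintf("g%02d", 1:20)
  tnb <- estimate_tech_noise(Matrix::Matrix(Xb, sparse = TRUE), n_bins = 2)
  expect_equal(unname(tnb$sigma_tech[1:10]), rep(sqrt(100 / 99), 10),
               tolerance = 1e-10)
  expect_equal(unname(tnb$sigma_tech[11:20]), rep(2 * sqrt(100 / 99), 10),
               tolerance = 1e-10)
})

test_that("raw disease score is the stated weighted average", {
  X <- Matrix::Matrix(matrix(c(1.0, 3.0,
                               2.0, 0.5), 2, 2, byrow = TRUE,
                             dimnames = list(c("gA", "gB"), c("c1", "c2"))),
                      sparse = TRUE)
  noise <- structure(list(sigma_tech = c(gA = 1, gB = 2)),
                     class = "TechNoiseModel")

  # single-gene set: score equals that gene's expression
  s1 <- raw_disease_score(X, make_gs("gA", 3.7), noise)
  expect_equal(s1, as.numeric(X["gA", ]))

  # equal omega and sigma: unweighted mean over the set
  noise_eq <- structure(list(sigma_tech = c(gA = 1, gB = 1)),
                        class = "TechNoiseModel")
  s2 <- raw_disease_score(X, make_gs(c("gA", "gB"), c(2, 2)), noise_eq)
  expect_equal(s2, as.numeric(Matrix::colMeans(X)))

  # hand arithmetic: omega = (2, 1), sigma = (1, 2)
  # w = (2, 0.5); S_c = (2 X_A + 0.5 X_B) / 2.5
  s3 <- raw_disease_score(X, make_gs(c("gA", "gB"), c(2, 1)), noise)
  expect_equal(s3, c((2 * 1 + 0.5 * 2) / 2.5, (2 * 3 + 0.5 * 0.5) / 2.5),
               tolerance = 1e-12)

  # invariance under positive rescaling of all weights
  s4 <- raw_disease_score(X, make_gs(c("gA", "gB"), c(20, 10)), noise)
  expect_equal(s3, s4, tolerance = 1e-12)

  # scores stay inside the per-cell expression range over the set
  expect_true(all(s3 >= pmin(X["gA", ], X["gB", ]) - 1e-12 &
                    s3 <= pmax(X["gA", ], X["gB", ]) + 1e-12))
})

test_that("control scores are matched, reproducible, and exchangeable", {
  set.seed(5)
  ng <- 60; nc <- 80
  X <- Matrix::Matrix(matrix(rpois(ng * nc, 3), ng, nc,
                             dimnames = list(sprintf("g%02d", 1:ng), NULL)),
                      sparse = TRUE)
  X <- X * 1.0
  noise <- estimate_tech_noise(X)
  gs <- make_gs(sprintf("g%02d", 1:10), rep(1, 10))

  # degenerate matching: pool restricted to the disease set itself;
  # every bin cell contains only its disease gene, so controls equal S_c
  S <- raw_disease_score(X, gs, noise)
  ctrl1 <- suppressWarnings(
    sample_control_scores(X, gs, noise, B = 1, seed = 1, pool = gs$genes,
                          n_mean_bins = 60, n_var_bins = 60))
  expect_equal(as.numeric(ctrl1$S_ctrl[, 1]), S, tolerance = 1e-12)

  # determinism: same seed reproduces the control matrix exactly
  c2 <- sample_control_scores(X, gs, noise, B = 10, seed = 99)
  c3 <- sample_control_scores(X, gs, noise, B = 10, seed = 99)
  expect_identical(c2$S_ctrl, c3$S_ctrl)

  # exchangeability: disease genes indistinguishable from the pool, so
  # mean control score tracks mean disease score
  c4 <- sample_control_scores(X, gs, noise, B = 200, seed = 7)
  expect_lt(abs(mean(c4$S_ctrl) - mean(S)) / abs(mean(S)), 0.05)
})

test_that("empirical cell p-values match a brute-force double loop", {
  # hand example: 3 cells, B = 2
  S <- c(2.0, -1.0, 0.5)
  C <- matrix(c(1.0, 0.0,
                -0.5, 1.5,
                0.25, 0.75), 3, 2, byrow = TRUE)
  ctrl <- structure(list(S_ctrl = C, B = 2), class = "ControlScores")
  sr <- cell_pvalues(S, ctrl)

  # independent oracle: per-cell normalization then the pooled double sum
  mu <- rowMeans(C); sd_ <- apply(C, 1, sd)
  Sn <- (S - mu) / sd_
  Cn <- (C - mu) / sd_
  p_expected <- vapply(1:3, function(cc) {
    cnt <- 0
    for (c2 in 1:3) for (b in 1:2)
      if (Sn[cc] <= Cn[c2, b]) cnt <- cnt + 1
    (1 + cnt) / (1 + 3 * 2)
  }, numeric(1))
  expect_equal(sr$p, p_expected, tolerance = 1e-12)
  expect_equal(sr$p_adj, p.adjust(p_expected, "BH"))

  # formula bounds are attained at the extremes
  hi <- cell_pvalues(c(10, 0, 0), ctrl)
  expect_equal(hi$p[1], 1 / (1 + 3 * 2))
  lo <- cell_pvalues(c(-10, 0, 0), ctrl)
  expect_equal(lo$p[1], 1)
  expect_true(all(sr$p >= 1 / (1 + 3 * 2) & sr$p <= 1))
  expect_true(all(sr$p_adj >= sr$p))
})

test_that("cell-type association handles the extremes", {
  sr <- data.frame(raw_score = rnorm(40), norm_score = rnorm(40),
                   p = rep(0.5, 40), p_adj = rep(1, 40),
                   significant = FALSE)
  a <- celltype_association(sr, rep(c("A", "B"), each = 20))
  expect_equal(a$prop_sig, c(0, 0))
  expect_equal(a$assoc_p, c(1, 1))

  sr2 <- sr; sr2$p <- 1e-4; sr2$p_adj <- 1e-3; sr2$significant <- TRUE
  a2 <- celltype_association(sr2, rep(c("A", "B"), each = 20))
  expect_equal(a2$prop_sig, c(1, 1))
  expect_lt(a2$assoc_p[1], 1e-10)
})

test_that("an injected cell-type effect is ranked first in most seeds", {
  # effect_log2 = 1 in one type: that type has the top significant share
  # heterogeneous base means: the matched-control bins must mix disease and
  # background genes, as they do in real data
  genes <- sprintf("g%03d", 1:300)
  dg <- genes[1:40]
  hits <- vapply(1:20, function(s) {
    set.seed(s * 17)
    bm <- exp(runif(300, log(0.5), log(4)))
    sp <- cellpop_spec(genes, bm, c("target", "other1", "other2"),
                       c(300, 300, 300), disease_genes = dg,
                       effect_log2 = 1, target_types = "target")
    cm <- normalize_expression(simulate_cells(sp, seed = s))
    noise <- estimate_tech_noise(cm$norm)
    gs <- make_gs(dg, rep(1, length(dg)))
    S <- raw_disease_score(cm$norm, gs, noise)
    ctrl <- sample_control_scores(cm$norm, gs, noise, B = 50, seed = s + 1000)
    sr <- cell_pvalues(S, ctrl)
    a <- celltype_association(sr, cm$cells$cell_type)
    metric <- a$prop_sig + 1e-9 * a$n_nominal  # nominal count breaks 0-0 ties
    a$cell_type[which.max(metric)] == "target"
  }, logical(1))
  expect_gte(sum(hits), 18)
})
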