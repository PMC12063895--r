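test_that("eQTL genotype QC drops low-info and low-MAF SNPs", {
  set.seed(1)
  g_common <- rbinom(400, 2, 0.3)
  g_rare <- c(rep(0, 396), 1, 1, 0, 0)   # MAF = 0.0025
  g_ok <- rbinom(400, 2, 0.4)
  p <- make_panel(cbind(g_common, g_rare, g_ok), info = c(0.69, 1, 1))
  qc <- genotype_qc_eqtl(p)
  expect_equal(qc$panel$variants$snp_id, "g_ok")
  expect_equal(qc$report$removed, c(1L, 1L))

  # an all-pass panel is returned unchanged
  p2 <- make_panel(cbind(g_common, g_ok))
  qc2 <- genotype_qc_eqtl(p2)
  expect_identical(qc2$panel$genotypes, p2$genotypes)
})

test_that("cis SNP extraction uses a closed window on the gene's chromosome", {
  set.seed(2)
  geno <- matrix(rbinom(8 * 50, 2, 0.3), 50, 8)
  pos <- c(1000, 499000, 500000, 600000, 900000, 1500000, 1501000, 2500000)
  p <- make_panel(geno, pos = pos)
  gene <- data.frame(gene_id = "g", chr = 1, start = 1000000, end = 1001000)
  sub <- extract_cis_snps(p, gene, cis_kb = 500)
  # window [500000, 1501000]: SNPs 3..7, boundaries included
  expect_equal(sub$variants$pos, pos[3:7])

  # brute-force interval oracle
  manual <- pos[pos >= gene$start - 5e5 & pos <= gene$end + 5e5]
  expect_equal(sub$variants$pos, manual)

  # another chromosome is never cis
  p22 <- make_panel(geno, chr = 22L, pos = pos)
  expect_message(r <- extract_cis_snps(p22, gene, cis_kb = 500), "no cis")
  expect_null(r)
})

test_that("Haseman-Elston cis-h2 behaves at the limits and recovers truth", {
  p <- simulate_genotypes(400, 20, block_size = 5, rho = 0.3, seed = 3)
  gene <- data.frame(gene_id = "g", chr = 1, start = 1, end = 40000)

  # noise-free expression: estimate close to 1 (clipped at 1)
  e0 <- simulate_pseudobulk_expression(
    p, gene, data.frame(snp_id = p$variants$snp_id[c(2, 7)], w_true = c(1, -0.5)),
    noise_sd = 0, seed = 1)
  h0 <- estimate_cis_h2(p, e0$expr, seed = 1)
  expect_gte(h0$cis_h2, 0.9)
  expect_lt(h0$p, 0.05)

  # pure noise: estimate near 0 and permutation p spread over (0, 1]
  raw <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    h <- estimate_cis_h2(p, rnorm(400), seed = s)
    c(h$slope_raw, h$p)
  }, numeric(2))
  expect_lt(abs(mean(raw[1, ])), 0.15)
  expect_gt(max(raw[2, ]) - min(raw[2, ]), 0.3)

  expect_error(estimate_cis_h2(p, rep(1, 400)), "constant")
})

test_that("cis-h2 recovers a 0.4 variance share across seeds", {
  shares <- vapply(1:20, function(s) {
    p <- simulate_genotypes(1000, 30, block_size = 5, rho = 0.4, seed = s)
    gene <- data.frame(gene_id = "g", chr = 1, start = 1, end = 60000)
    cw <- data.frame(snp_id = p$variants$snp_id[8], w_true = 1)
    e <- simulate_pseudobulk_expression(p, gene, cw,
                                        noise_sd = sqrt(1 / 0.4 - 1),
                                        seed = s + 300)
    estimate_cis_h2(p, e$expr, n_perm = 50, seed = s)$cis_h2
  }, numeric(1))
  expect_gt(mean(shares), 0.25)
  expect_lt(mean(shares), 0.55)
})

test_that("weight training identifies a single strong cis SNP", {
  p <- simulate_genotypes(500, 12, block_size = 3, rho = 0.2, seed = 5)
  causal <- 5
  expr <- scale(p$genotypes[, causal]) + rnorm(500, sd = 0.05)
  m <- fit_weights(p, expr, seed = 1, inner_nfolds = 3)
  expect_s3_class(m, "CisModel")
  expect_gt(m$cv_r2[["top1"]], 0.95)
  expect_equal(which.max(abs(m$weights$top1)), causal)
  expect_gt(m$cis_h2, 0.7)
  expect_equal(m$best_method,
               names(m$cv_r2)[max(which(m$cv_r2 == max(m$cv_r2)))])
})

test_that("null expression is rejected in almost all seeds", {
  rejected <- vapply(1:20, function(s) {
    p <- simulate_genotypes(300, 10, block_size = 5, rho = 0.3, seed = s + 40)
    set.seed(s)
    is.null(suppressMessages(
      fit_weights(p, rnorm(300), seed = s, inner_nfolds = 3)))
  }, logical(1))
  expect_gte(sum(rejected), 18)
})

test_that("a polygenic cis signal favors shrinkage learners over top1", {
  wins <- vapply(1:20, function(s) {
    p <- simulate_genotypes(1000, 30, block_size = 5, rho = 0.3, seed = s + 80)
    set.seed(s)
    idx <- 1:10
    w <- rnorm(10)
    g <- scale(p$genotypes[, idx]) %*% w
    g <- g / sd(g) * sqrt(0.5)
    expr <- g + rnorm(1000, sd = sqrt(0.5))
    m <- suppressMessages(fit_weights(p, expr, seed = s, inner_nfolds = 3))
    if (is.null(m)) return(NA)
    max(m$cv_r2[c("ridge_blup", "enet")]) > m$cv_r2[["top1"]]
  }, logical(1))
  expect_gte(sum(wins, na.rm = TRUE), 15)
})

test_that("TWAS z reduces to its closed forms and matches hand arithmetic", {
  # single-SNP model, weight 1: z_twas equals the SNP's GWAS z exactly
  ss <- make_ss(c("s1", "s2", "s3"), z = c(1.7, -0.8, 2.4))
  m1 <- make_cis_model("s2", 1)
  r1 <- twas_assoc(m1, ss, matrix(1, 1, 1))
  expect_identical(r1$z_twas, -0.8)

  # identity reference LD: z = w'z / ||w||
  w <- c(0.5, -1, 2)
  m3 <- make_cis_model(c("s1", "s2", "s3"), w)
  r3 <- twas_assoc(m3, ss, diag(3))
  expect_equal(r3$z_twas, sum(w * c(1.7, -0.8, 2.4)) / sqrt(sum(w^2)),
               tolerance = 1e-12)

  # 3-SNP hand example with a dense R
  R <- matrix(c(1, 0.5, 0.2,
                0.5, 1, 0.4,
                0.2, 0.4, 1), 3, 3)
  num <- 0.5 * 1.7 + (-1) * (-0.8) + 2 * 2.4
  den <- sqrt(drop(t(w) %*% R %*% w))
  r4 <- twas_assoc(m3, ss, R)
  expect_equal(r4$z_twas, num / den, tolerance = 1e-12)
  expect_equal(r4$p, 2 * pnorm(-abs(num / den)), tolerance = 1e-12)
})

test_that("TWAS is invariant to allele flips and handles missing SNPs", {
  ss <- make_ss(c("s1", "s2", "s3"), z = c(1.7, -0.8, 2.4))
  w <- c(0.5, -1, 2)
  m <- make_cis_model(c("s1", "s2", "s3"), w)
  R <- diag(3)
  base <- twas_assoc(m, ss, R)

  # flip a1/a2 and the beta sign of one record: z_twas unchanged
  rec <- ss$records
  rec$a1[2] <- "G"; rec$a2[2] <- "A"
  rec$beta[2] <- -rec$beta[2]; rec$z[2] <- -rec$z[2]
  flipped <- twas_assoc(m, sumstats(rec, trait_id = "t"), R)
  expect_equal(flipped$z_twas, base$z_twas, tolerance = 1e-12)

  # a SNP absent from the summary stats is dropped with a warning
  expect_warning(r2 <- twas_assoc(m, sumstats(rec[-3, ], trait_id = "t"), R),
                 "missing")
  expect_equal(r2$z_twas,
               sum(w[-3] * c(1.7, -0.8)) / sqrt(sum(w[-3]^2)),
               tolerance = 1e-12)
  expect_error(
    suppressWarnings(twas_assoc(m, sumstats(rec[0, ], trait_id = "t"), R)),
    "matched")

  # near-singular variance is floored with a warning
  m0 <- make_cis_model(c("s1", "s2"), c(1, -1))
  Rs <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_warning(twas_assoc(m0, ss, Rs), "floored")
})

test_that("BH adjustment equals the textbook step-up procedure", {
  one <- adjust_results(data.frame(gene_id = "g", cell_type = "T",
                                   trait_id = "t", z_twas = 2.05, p = 0.04))
  expect_equal(one$p_adj, 0.04)
  expect_true(one$nominal_sig && one$study_sig)

  all1 <- adjust_results(data.frame(gene_id = letters[1:4], cell_type = "T",
                                    trait_id = "t", z_twas = 0, p = 1))
  expect_false(any(all1$nominal_sig) || any(all1$study_sig))

  set.seed(8)
  pv <- round(runif(20), 3)
  res <- adjust_results(data.frame(gene_id = sprintf("g%d", 1:20),
                                   cell_type = "T", trait_id = "t",
                                   z_twas = 0, p = pv))
  # textbook step-up computed by hand: sort, p(i) * m / i, cumulative min
  # from the largest rank down, mapped back to the original order
  o <- order(pv)
  stepup <- pv[o] * 20 / seq_len(20)
  for (i in 19:1) stepup[i] <- min(stepup[i], stepup[i + 1])
  stepup <- pmin(stepup, 1)
  expect_equal(res$p_adj[o], stepup, tolerance = 1e-12)
})

test_that("pseudo-bulk aggregation is per individual and inverse-normal", {
  set.seed(9)
  counts <- matrix(rpois(20 * 60, 4), 20, 60,
                   dimnames = list(sprintf("g%02d", 1:20), NULL))
  cm <- normalize_expression(
    make_cm(counts, cell_type = rep(c("T", "B"), each = 30)))
  ids <- rep(sprintf("i%d", 1:10), 6)
  pb <- pseudobulk_from_cells(cm, ids, "T")
  expect_equal(dim(pb), c(20, 10))
  # each gene's transformed values are a fixed quantile ladder
  expect_equal(unname(sort(pb[1, ])), unname(sort(pb[2, ])),
               tolerance = 1e-12)
  expect_equal(mean(pb[1, ]), 0, tolerance = 1e-12)
})
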