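---
title: "Methods: from microbial-abundance GWAS to cell-type-specific genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from microbial-abundance GWAS to cell-type-specific genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

florascore chains seven stages that together connect GWAS summary statistics
for upper-respiratory microbial-abundance traits to immune-cell types and
cell-type-specific genes in severe influenza-like illness (ILI): summary-
statistic QC, LD-score-regression heritability gating, gene-level
association, per-cell disease-relevance scoring, cis-eQTL weight training
with summary-based TWAS, Wilcoxon differential expression, and
over-representation analysis. This vignette states each stage's model, its
assumptions, the tunable parameters, and the numerical and design choices
that were genuinely open.

## Summary-statistic QC and the heritability gate

Input tables carry one record per SNP (SNP, CHR, BP, A1, A2, BETA, SE, N,
FRQ). `qc_filter()` applies six rules in a fixed order: autosomes 1-22 only;
per-SNP sample size at least 70% of the trait's maximum reported N (the
denominator is a choice — the rule's reference population is not observable
from a summary table); alleles in A/C/G/T; summary variance anomalies
(non-finite beta or se^2 <= 0 — the only per-record variance available is
se^2); se > 0; minor-allele frequency >= 0.001. The filter is idempotent and
its per-rule tallies reconcile with the record counts, which the tests
assert.

Heritability is estimated by LD-score regression: with chi2_j = z_j^2,

    E[chi2_j] = 1 + (N_j * h2 / M) * l_j,

where l_j is SNP j's LD score, `compute_ld_scores()` returns
l_j = sum over the window of r2_adj with the small-sample correction
r2_adj = r2 - (1 - r2)/(n - 2) (scores may dip below 1 — the correction is
unbiased, not truncated). The regression is weighted least squares with
weights 1/max(l_j, 1), and the standard error comes from a 20-block
delete-one jackknife. Traits pass the gate iff h2 > 0.1, strictly.

Two numerical caveats the tests make explicit:

* With a constant chi2 response the slope is exactly 0 by definition; with a
  constant LD-score predictor the slope is not identifiable and the function
  refuses rather than returning an arbitrary number.
* The slope is only as identified as the *spread* of LD scores. Equal-size
  equicorrelated LD blocks at a single correlation give nearly constant l_j
  and therefore a noisy slope; this is a property of the estimator, not of
  the implementation. Where the simulation design is open, the calibration
  tests use per-block correlations cycling over several levels so l_j
  varies. The default LD window is 1 Mb (a convention; no value is implied
  by the estimator itself).

## Gene-level association

`gene_statistic()` implements the snp-wise mean model: the statistic is the
mean chi-square over a gene's SNPs, whose null given the local LD
correlation matrix R is (1/k) * sum(lambda_i * chi2_1) with lambda_i the
eigenvalues of R. The upper-tail p-value is computed exactly: when the
nonzero eigenvalues are (numerically) equal the null is a scaled chi-square
and the closed form is used — k = 1 and R = identity reduce to this — and
otherwise Davies' algorithm for positive weighted chi-square sums
(`mgcv::psum.chisq`, about 0.1 ms per gene). A two-moment (Satterthwaite)
gamma approximation is retained only as a fallback should the Davies
evaluation fail, because its tail is materially off for skewed spectra: at
k = 5 with equicorrelation 0.7 it underestimates p by ~21% at p = 0.01 and
~50% at p = 0.001, which would distort precisely the gene-ranking tail this
stage exists for. Negative eigenvalues from numerically non-PSD inputs are
clipped at zero with a warning. An exact-null Monte-Carlo evaluation is
available (`mc_draws`) and serves as the test oracle: the analytic tail
agrees with a 10^6-draw Monte-Carlo within 10% relative error over p in
[0.001, 0.5]. Genes are annotated to SNPs with a symmetric 10 kb
window (closed interval); the window size is a convention, not an estimate.
The probit transform z_gene = qnorm(1 - p) is computed on the upper tail
with p clipped at 1e-300 so z stays finite. The disease gene set is the
top-k genes by z_gene (default k = 1000), ties broken lexicographically by
gene id so the set is deterministic, with weights omega_g = z_gene.

## Per-cell disease-relevance scoring

Expression is normalized as X_cg = log(1 + 1e4 * count/total) (log1p
counts-per-10k). Clustering-oriented normalizations operate upstream of
scoring and are out of scope; log1p-CP10K is the scoring convention adopted
here. Gene-specific technical noise sigma_tech,g is the square root of the
bin-median variance over 20 equal-size mean-expression bins, floored at
1e-4; genes with identical means share a bin (min-rank binning) and hence a
sigma.

The raw per-cell score is the stated weighted average

    S_c = sum_g omega_g sigma_g^-1 X_cg / sum_g omega_g sigma_g^-1 ,

invariant to positive rescaling of the weights; negative omega_g are clipped
at zero (a z < 0 gene should not be in a top-k set, but clipping makes the
behavior defined). B Monte-Carlo control gene sets are drawn by replacing
each disease gene with a uniform draw from its (20 mean-bins x 5
variance-bins) cell, carrying the disease gene's omega while contributing
its own sigma; empty cells fall back to the nearest nonempty mean bin within
the variance bin.

The empirical p-value pools normalized control scores:

    P_c = (1 + #{(c', b): S_c <= S_ctrl(c', b)}) / (1 + n_cell * B),

so 1/(1 + n_cell*B) <= P_c <= 1 by construction. The normalization recipe is
the package's largest judgment call: each cell's raw score is centred and
scaled by the mean and sd of its own B control scores, and the control
scores are normalized the same way, before pooling. This per-cell
normalization absorbs cell-level covariates (sequencing depth) and is
isolated in `cell_pvalues()` so an alternative (gene-set-level
normalization) could be swapped without touching the rest. With B = 1 the
per-cell sd is undefined and raw scores are compared directly.

Cell-type association: per type, the proportion of cells significant after
BH (p_adj < 0.05) is reported together with a one-sided binomial test of the
count of nominally significant cells (P_c < 0.05) against expectation 0.05.
The binomial test is a choice — only adjusted per-type p-values are
conventionally reported, with no canonical test — and BH is applied across
(cell type x trait) pairs at the pipeline level.

A fixture caveat the power test encodes: matched controls only carry
information when the matching bins mix disease and background genes. If all
background genes share one mean, upregulated disease genes occupy the top
bins alone and become their own controls; the generator therefore draws
per-gene base means from a log-uniform spread (0.5 to 4), as real data
would.

## cis-eQTL weights and TWAS

Pseudo-bulk expression per (individual x cell type) is the mean of
normalized expression over the individual's cells of that type,
inverse-normal transformed across individuals (Blom offset) before model
fitting; the aggregation recipe is a convention choice. cis SNPs are taken
from a closed +-500 kb window around the gene. cis heritability uses
Haseman-Elston regression — the off-diagonal products of standardized
expression regressed on the cis GRM (XX'/m on standardized dosages) — which
is closed-form and fast at these scales; its p-value is a 200-draw
permutation of expression. Estimates are clipped to [0, 1]. REML would be
the likelihood-based alternative; at desk scale HE is adequate and
dependency-free.

Genes passing the cis-h2 gate (permutation p < 0.05, configurable) get four
learners: top1 (best marginal SNP), ridge regression, lasso, and elastic net
(alpha = 0.5), penalties by inner cross-validation. cv_r2 is the *signed*
squared correlation between out-of-fold predictions and expression
(sign(r) * r^2, 0 for constant predictions): a plain square can never be
negative, so anti-correlated out-of-fold predictions could not be rejected;
the signed version makes "all cv_r2 <= 0 means reject" meaningful. Ties for
best method resolve toward the later entry in top1 < ridge < lasso < enet.
Final weights are refit on all samples.

TWAS combines the weights with GWAS z-scores under reference LD:

    z_twas = w'z / sqrt(w' R w),

with allele-swapped records sign-flipped, irreconcilable or missing SNPs
dropped with warnings, and the variance floored at 1e-8 (with a warning)
when near-singular. Two-sided normal p-values are BH-adjusted over the full
(gene x cell type x trait) table; nominal (p < 0.05) and study-wide
(p_adj < 0.05) flags are both kept, since cross-population weight transfer
argues for reporting nominal hits.

## Differential expression and over-representation

Within a cell type, severe-vs-mild differences per gene use
`stats::wilcox.test` — exact for small untied samples, tie-corrected normal
approximation otherwise — so the 6-observation oracle test agrees with
exhaustive enumeration while large inputs use the approximation. The fold
change is computed on de-logged normalized means with a 1e-9 pseudocount,
log2((mean expm1 severe + eps)/(mean expm1 mild + eps)); a gene is a DEG iff
BH-adjusted p < 0.05 and |log2FC| > 0.25. BH is applied within (cell type x
trait).

Over-representation uses the exact hypergeometric upper tail after
intersecting each term with the universe; `enrichment_ratio` is
overlap/query_size — the convention that reproduces reported ratios such as
1/6 = 0.167 and 1.0 — and zero-overlap terms are dropped before BH. The
universe defaults to the genes tested for differential expression in the
cell type at hand; the choice of universe (all genes vs expressed genes) is
configurable because no single convention exists.

## The synthetic-data generator

Every pipeline input can be generated with known ground truth:

* **Genotypes**: a Gaussian copula with equicorrelation rho inside
  fixed-size blocks and independence between blocks, thresholded per
  haplotype at qnorm(maf), so MAF is controlled exactly in expectation and
  the block LD structure is analytically known. `rho` may vary per block.
  MAFs are uniform on (0.05, 0.5) by default.
* **Traits**: y = X_std beta + e with betas rescaled so the realized genetic
  variance share equals h2 exactly; the share is recorded next to the trait.
  The microbial-abundance trait scale is modeled as Gaussian — the actual
  scale (transformed abundance vs presence) is not observable from summary
  statistics, and this is recorded as an assumption.
* **Cells**: negative-binomial counts, var = mu + mu^2/size with size = 10
  (moderate overdispersion), log-uniform base means, disease genes
  multiplied by 2^effect_log2 in target cell types, and an optional severe-
  group effect for the DEG stage. effect_log2 = 0 reproduces the null
  exactly.
* **Pseudo-bulk expression**: standardized cis dosages times true weights
  plus Gaussian noise, with the realized cis share recorded.

`simulate_study()` links them into one end-to-end fixture: two traits, both
passing the h2 gate, where only the *signal* trait's concentrated effects
sit in genes that are simultaneously upregulated in one target cell type
(CD16+ monocytes in the fixture) and given true cis-eQTL effects. Its
traits mix a genome-wide polygenic background (60% of genetic variance)
with block-concentrated effects (40%) because LD-score regression assumes
the infinitesimal model: concentrated variance makes a handful of blocks
leverage points, and — a property worth knowing — a trait whose per-SNP
heritability is elevated inside high-LD blocks yields an LDSC slope above
its true genome-wide h2. In the fixture this inflation only makes the gate
a reliable pass-through; the unbiased-recovery claims are tested on purely
polygenic traits.

Two further design points in the linked fixture. First, the control trait's
polygenic background is zeroed inside the cis windows of the
expression-modeled genes: a background effect at a modeled cis SNP acts on
the trait *through* genetically predicted expression, so TWAS hits it
produces are true mediation, not false positives — a negative-control trait
must not carry them. Second, the number of Monte-Carlo control sets matters
for calibration beyond the p-value floor: each cell's score is standardized
by a standard deviation estimated from its own B control scores, and since
E[sigma/sigma_hat] > 1, small B leaves the normalized disease scores
slightly overdispersed relative to the normalized controls — at B = 100 the
nominal rate sits near 0.065 rather than 0.05, which the binomial
cell-type-association test then amplifies. The fixture uses B = 300 (the
production default is 1000).

What the generator does *not* emulate: realistic recombination maps or
haplotype sharing, imputation artifacts, ambient RNA, doublets, batch
effects, cell-type-specific library-size differences, or non-Gaussian trait
scales. Passing tests therefore demonstrate correctness of the statistical
machinery under its stated assumptions, not robustness to those artifacts.

## Problem sizes and runtime choices

The test and acceptance runs use desk-scale sizes chosen to keep each
stochastic check tight enough to be meaningful: LDSC recovery at n = 5000
individuals and M = 2000 SNPs over 20 seeds; gate separation on one n =
5000, M = 1000 panel with 20 traits per group; per-cell scoring nulls at
2000 cells and B = 100 controls; TWAS null calibration from 50 trained
models by 20+ permuted traits (>= 1000 z-scores); DEG nulls at 2000 genes
by 400 cells; the end-to-end study at 800 individuals, 300 SNPs, 1200
cells, B = 300. These sizes are the package's own choices; all scale
linearly upward.

## Known limitations

* LDSC at desk scale is noisy when LD scores vary little; the per-seed
  spread of the slope can reach +-0.25 at M = 2000 under homogeneous
  blocks. The gate criterion (h2 > 0.1) tolerates this; precise h2
  estimation does not.
* The scoring stage's control matching assumes the disease gene set is not
  systematically extreme in mean expression relative to the pool.
* TWAS assumes the reference LD matches the GWAS population; allele
  harmonization handles strand-consistent swaps only (no strand flips).
* The cis-h2 permutation gate at 200 draws bounds the attainable p at
  1/201, which is sufficient for a 0.05 gate but not for finer claims.
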