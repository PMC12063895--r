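Package: florascore
Title: Linking Upper-Respiratory Flora GWAS Signals to Immune Cell Types and Cell-Type-Specific Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable inference chain connecting microbial-abundance GWAS
    summary statistics to immune-cell types and cell-type-specific genes in
    severe influenza-like illness. Stages: summary-statistic quality control,
    LD-score-regression heritability estimation with an h2 gate, gene-level
    association with an LD-aware weighted chi-square null, per-cell disease
    relevance scoring against Monte-Carlo matched control gene sets,
    cis-eQTL weight training with summary-based transcriptome-wide
    association, Wilcoxon differential expression, and hypergeometric
    over-representation analysis. A synthetic-data module generates every
    input with known ground truth for parameter-recovery and calibration
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    glmnet,
    mgcv,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
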