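Package: qcpop
Title: Genotyping-Array Quality Control and Population-Structure Analysis for
    Large Biobank Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a genotyping-array quality-control and
    population-genetics pipeline for large cohort studies: variant-level QC
    (plate and batch genotype-calling effect tests with empirically derived
    fail rules, region-stratified Hardy-Weinberg testing, reference allele
    frequency concordance, duplicate probeset resolution), sample-level QC
    (region-standardised heterozygosity with a runs-of-homozygosity rescue
    rule, sex inference and chromosome-X aneuploidy karyotyping from LRR/BAF
    intensity summaries, plate-orientation error tracing, ancestry outliers,
    duplicate discovery), pairwise relatedness (method-of-moments IBD,
    KING-robust kinship, relationship classification, pedigree-expected IBD,
    greedy unrelated-set selection), population structure (LD pruning, PCA,
    BIC-based informative-PC selection, an iterative hidden-Markov-model
    detector of long-range-LD regions in PC loadings, robust Mahalanobis
    ancestry outliers, Weir-Cockerham Fst), and GWAS preparation
    (representative-subset construction, effective minor-allele-count
    filtering, logistic association scan with Firth fallback, LD clumping,
    region-stratified meta-analysis). A synthetic-cohort simulator with
    ground-truth labels supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    nnet,
    mclust,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
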