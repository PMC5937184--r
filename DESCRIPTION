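Package: behavarch
Title: Comparative Genetic Architecture of Behavioral Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of the genetic architecture of
    behavioral traits. Implements meta-analysis of QTL effect sizes across
    behavioral categories (rank tests, permutation nulls, frequentist and
    Bayesian linear mixed models ranked by DIC), genomic-relatedness-matrix
    construction and single-component GREML estimation of SNP heritability,
    per-trait single-SNP association scans with pleiotropy and effect-size
    matrices, and a permutation test for directionality in trait pairs based
    on cross-correlations of SNP effect sizes. Includes seeded synthetic-data
    generators for QTL meta-tables and inbred-line genotype/phenotype panels,
    and readers/writers for plink bed/bim/fam, VCF, and .phen formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
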