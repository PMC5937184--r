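# behavarch

Comparative analysis of the genetic architecture of behavioral traits, in
two arms that mirror how the question is studied in practice:

1. **Across species** — meta-analysis of compiled QTL tables, where each
   locus reports its effect size as percent phenotypic variance explained
   (PVE). Do behavioral categories (courtship, feeding, emotion, social,
   ...) differ systematically in effect size once study-level confounders
   (sample size, evolutionary divergence, cross type) are accounted for?
   Tools: LOD → p conversion via the 1-df chi-square equivalence
   (statistic `2·ln(10)·LOD`), category summaries, two-group
   Kruskal–Wallis tests (chi-square or exact enumeration), permutation
   nulls built by resampling the complement without replacement,
   divergence/effect Pearson correlation on log10(years), REML linear
   mixed models (`lme4`), and an in-package Gibbs sampler for the Bayesian
   mixed model with inverse-gamma variance priors, HPD intervals,
   Gelman–Rubin diagnostics and DIC-based ranking of random-effect
   structures.
2. **Within a population** — architecture among inbred, fully genotyped
   lines (a DGRP-style panel): genomic relatedness matrices (GCTA-style
   per-SNP standardization, with the inbred-panel variant auto-detected),
   single-component GREML heritability (`y ~ N(μ1, Vg·A + Ve·I)`, AI-REML
   with EM warm start), per-trait single-SNP association scans, binary
   pleiotropy matrices and SNP × trait effect-size matrices with their
   Spearman trait structure, and a permutation test for trait-pair
   directionality: with `x_cor = ρ(xx, xy)` and `y_cor = ρ(yy, yx)` over
   each trait's significant-SNP effect vectors,

   ```
   D = |1 − |x_cor − y_cor||
   ```

   where **small D** separates mediated architectures (`G → P1 → P2`)
   from symmetric pleiotropy (`P1 ← G → P2`).

Seeded synthetic-data generators (`gen_qtl_table()`, `gen_genotypes()`,
`gen_phenotypes()`) emulate both kinds of input — a 1007-locus compiled
QTL table with courtship-elevated effect sizes, and additive inbred-line
panels with fork/chain pleiotropy — so the full pipeline runs and is
tested without any external download. Readers/writers cover the working
formats: plink bed/bim/fam (bit-exact round trip), VCF, `.phen` phenotype
files, and a validated QTL CSV schema.

## Worked example

```r
library(behavarch)

# -- meta-analysis arm on the bundled synthetic compiled table ----------
tab <- gen_qtl_table(qtl_sim_config(seed = 1))
s <- summarize_by_category(tab)
head(s[order(-s$mean_pve), ], 4)
#>  category n_loci mean_pve median_pve fraction_pve_below_20
#> courtship    124    23.39      15.23                 0.581
#>     (all)   1007     9.80       5.35                 0.870
#>  wariness    109     9.50       5.96                 0.890
#> migration    109     9.21       4.31                 0.881

category_vs_rest_test(tab, "courtship")
#> courtship vs rest: H = 85.8, p = 1.95e-20
permutation_category_test(tab, "courtship", n_perm = 10000, seed = 1)
#> permutation: observed mean 23.39, p = 0

# -- heritability arm: recover a simulated h2 of 0.5 --------------------
cfg <- panel_sim_config(n_lines = 1000, n_snps = 5000, seed = 2,
  traits = list(trait_spec("startle", causal_snps = 1:50, beta = 1, h2 = 0.5)))
panel <- gen_genotypes(cfg)
phen  <- gen_phenotypes(panel, cfg)
greml_fit(build_grm(filter_maf(panel, 0.01)),
          setNames(phen$startle, phen$line_id))
#> GREML: h2 = 0.5227 (SE 0.0988), Vg = 37.75, Ve = 34.47, p = 2.83e-07 [converged]
```

Reading the output: the synthetic table reproduces its configured study
conditions — a global mean PVE near 9.5% with ~87% of loci under 20%,
and courtship loci carrying roughly three-fold larger effects, flagged by
both the rank test and the permutation null (p = 0 means no permuted
complement mean exceeded the observed courtship mean in 10,000 draws).
The GREML fit recovers the simulated heritability (0.52 ± 0.10 against a
target of 0.5) with a strongly significant likelihood-ratio test against
`Vg = 0`.

End-to-end runs (simulate → meta → GRM → GREML → GWAS → pleiotropy →
direction) go through `run_pipeline(run_config(...))`, which writes TSV
artifacts, a log, and a JSON summary embedding every seed and threshold.

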