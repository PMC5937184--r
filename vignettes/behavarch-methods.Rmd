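---
title: "Methods: comparative genetic architecture of behavioral traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genetic architecture of behavioral traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`behavarch` asks two related questions about the genetics of behavior. At
the *comparative* scale: do categories of behavior (courtship, feeding,
emotion, ...) differ systematically in the effect sizes of the loci mapped
for them across species? At the *population* scale: how heritable are
behavioral traits within a panel of inbred lines, how pleiotropic are their
variants, and can the direction of trait-to-trait relationships be read
off the cross-correlations of SNP effect sizes? This vignette documents
the models, the numerical choices, and the boundaries of what the bundled
synthetic data can and cannot demonstrate. The package is driven from R:
the exported functions and `run_pipeline()` (a staged driver that writes
TSV/JSON artifacts with full seed provenance) are the interface.

## The meta-analysis arm

The unit of observation is one significant QTL, carrying its effect size
as percent phenotypic variance explained (PVE, in (0, 100]), a
significance score, a behavioral category, and cross metadata (species
pair, cross type, sample size, generations and years diverged). Because
studies report significance on different scales, LOD scores are converted
through the interval-mapping equivalence: a LOD of $L$ corresponds to a
likelihood-ratio statistic $2\ln(10)\,L$ on one degree of freedom, so
`lod_to_neglog10p()` returns $-\log_{10} \Pr(\chi^2_1 > 2\ln(10) L)$,
computed on the log scale so large LODs do not underflow.

Category contrasts use three complementary tools:

* **Rank tests.** `category_vs_rest_test()` is the two-group
  Kruskal–Wallis test (midrank ties correction) of one category's PVE
  against all remaining loci. The default p-value is the chi-square
  approximation, the convention under which very small p-values on
  1000-locus tables are meaningful. For small tables `exact = TRUE`
  enumerates all group assignments of the H statistic instead; the exact
  path is validated against a brute-force oracle in the tests. The two
  p-values answer slightly different questions and are not
  interchangeable — the exact path is the defensible choice below a few
  dozen loci.
* **Permutation nulls.** `permutation_category_test()` draws, without
  replacement, samples of the category's size from the complement's PVE
  values and uses the sample means as the null for the observed category
  mean. The p-value is the literal count $\#\{\bar x_{null} >
  \bar x_{obs}\}/B$ with no add-one correction; the small-sample-safe
  $(b+1)/(B+1)$ variant sits behind `plus_one = TRUE`. Draw size equals
  the category size — the only choice that makes the null mean comparable
  to the observed one.
* **Mixed models.** `fit_lmm_effects()` fits PVE on category (fixed
  effect) by REML via `lme4`, with a configurable random structure
  defaulting to a per-study random intercept plus *independent* random
  slopes for centered-and-scaled sample size and log10 generations:
  "random slopes and intercepts" for two continuous covariates is only
  well-posed once a grouping factor is named, and the study is the
  natural exchangeable unit. Singular fits (a variance component at zero)
  are flagged separately from optimizer non-convergence.

`divergence_effect_correlation()` is a Pearson correlation of
$\log_{10}(\text{years diverged})$ against PVE — divergence spans four
orders of magnitude, so the log scale is the only sensible axis.

### The Bayesian arm and DIC

`fit_bayes_lmm()` implements the same Gaussian mixed model as a conjugate
Gibbs sampler written in-package: flat prior on fixed effects,
$\mathrm{IG}(0.001, 0.001)$ priors on every variance component, and
scalar full conditionals for the random effects (each random term's
design columns are orthogonal across grouping levels, so no large solves
are needed). Reported are posterior means, 95% highest-posterior-density
intervals (shortest sorted-sample interval), the Gelman–Rubin PSRF across
independent chains, and DIC computed as $\bar D + p_D$ with
$p_D = \bar D - D(\hat\theta)$ evaluated at the posterior means of all
location parameters and the residual variance. `rank_models_by_dic()`
fits the seven non-empty subsets of \{sample-size slope, generations
slope, cross-type intercept\} — each on top of the per-study intercept —
and orders them by DIC. Function defaults follow the conventional long
chains (300,000 iterations, 10,000 burn-in, thin 10, five chains); the
test suite and the acceptance script use shorter chains (a few thousand
iterations, three chains) that already pass the PSRF check on these data,
and a PSRF above 1.1 on any parameter attaches a convergence warning
rather than failing silently.

## The within-population arm

### GRM and GREML

`build_grm()` uses the per-SNP standardized estimator
$A_{jk} = m^{-1}\sum_i (x_{ij}-2p_i)(x_{ik}-2p_i)/v_i$ with missing
dosages mean-imputed per SNP (imputed entries contribute zero). The
denominator $v_i$ is $2p_i(1-p_i)$ for Hardy–Weinberg dosages, but a
fully inbred panel (every dosage 0 or 2) has per-SNP variance
$4p_i(1-p_i)$; `build_grm()` detects that case and standardizes
accordingly (`inbred = "never"` forces the outbred form). Without this
the GRM diagonal sits near 2 and heritability estimates halve — the
inbred normalization is what makes the estimator's $V_g$ live on the
phenotypic scale for line panels. MAF filtering (`filter_maf()`) is
exclusive at the threshold: a SNP at exactly the cutoff is removed.

`greml_fit()` estimates $y \sim N(\mu 1, V_g A + V_e I)$ by REML. The
model is rotated through the eigenbasis of $A$ (cached on the GRM by
`grm_decompose()` when many traits share one matrix), making every
iteration $O(n)$ after one $O(n^3)$ decomposition. Optimization is three
EM-REML warm-start steps followed by average-information updates;
an AI step that leaves the feasible region is clamped to a small floor
($10^{-8} V_p$, flagged as a boundary solution) and EM is the fallback
when the AI matrix is singular. Convergence is $|\Delta \log L| <
10^{-8}$ with a 100-iteration cap. The EM phase provably never decreases
the restricted likelihood, and the tests assert that monotonicity on the
iteration trace. Standard errors of $h^2 = V_g/V_p$ come from the delta
method on the inverse AI matrix; the test against $V_g = 0$ uses the
50:50 $\chi^2_0/\chi^2_1$ boundary mixture. Estimation at the $h^2 = 0$
boundary is truncated at zero, so the null-trait estimate has a positive
half-normal excess of roughly $\mathrm{se}/\sqrt{2\pi}$ (about 0.05 at
1000 lines and 5000 SNPs) — a property of any nonnegative variance
estimator, visible in the parameter-recovery study. Fits use an
intercept-only fixed part; covariates are out of scope.

### Association scans and pleiotropy

`assoc_scan()` is the basic quantitative association test: per SNP,
simple regression of the (line-mean) phenotype on dosage, two-sided t on
$n-2$ df, vectorized over SNPs, with per-SNP missing-data handling and
zero-variance SNPs flagged untestable rather than aborting. No
relatedness correction or genomic control is applied — matching the
analysis this package reimplements; treat scan p-values accordingly.
Replicate measures are averaged per line first
(`aggregate_replicates()`). Hit sets (strict `p < threshold`) feed the
binary pleiotropy incidence (SNPs significant for ≥ 2 traits, plus genes
carrying ≥ 2 such SNPs given an annotation map) and the effect matrix:
rows are the union of all hit sets, entry $(s, t)$ the beta of SNP $s$ in
trait $t$'s scan whether or not $s$ is significant for $t$. Trait
structure over that matrix is pairwise-complete Spearman correlation.

### Trait-pair directionality

For traits $x, y$ with significant SNP sets $s_1, s_2$: `xx`/`xy` are the
effect sizes at $s_1$ for $x$ and $y$, `yy`/`yx` those at $s_2$, and

$$x_{cor} = \rho(xx, xy), \quad y_{cor} = \rho(yy, yx), \quad
D = |1 - |x_{cor} - y_{cor}||.$$

Small $D$ is the directional signature: a genotype reaching $y$ only
through $x$ ($G \to P_1 \to P_2$) makes $x$'s SNPs predictive of $y$
(high $|x_{cor}|$) while $y$'s own SNPs say nothing about $x$
($y_{cor} \approx 0$); symmetric pleiotropy ($P_1 \leftarrow G \to P_2$)
makes the two cross-correlations similar and $D \approx 1$. Pairs enter
only when both traits have strictly more than three significant SNPs.
The permutation p-value independently permutes all four vectors, recomputes
$D$, and counts $\#\{D_{obs} > D_{perm}\}/B$ — ties count toward the
null. When fewer distinct outcomes than permutations exist (vectors of
length ≤ 6) the exact distribution is enumerated instead; it factorizes
over the two correlations, so enumeration costs $n_1! + n_2!$ correlation
evaluations rather than their product. Screening — one cross-correlation
above 0.5 and the other below 0.1 — is applied to *absolute* values
(a strong negative correlation is a strong correlation), and
Bonferroni adjustment multiplies by the number of pairs actually tested.
Both orderings of an ambiguous pair are reported rather than silently
choosing one.

## The synthetic data and what it shows

The generators define the study conditions everything else is tested
under; they are deliberately simple and their gaps matter.

* `gen_qtl_table()` defaults emulate a 1007-locus compiled table over ten
  categories and 114 studies: courtship (124 loci, mean PVE 22%) about
  three-fold above the background categories (8.2%), feeding elevated
  (11 loci, 18%), emotion and social depressed (5.5% / 6.5%) — chosen so
  the analytic global mean is ~9.5% with ~88% of loci under 20% PVE.
  Per-category PVE is exponential (truncated to (0, 100] by resampling),
  the many-small/few-large architecture expected for behavior. Divergence
  shifts per-locus mean PVE by 2.5 points per decade of years diverged
  (centered, so category means are preserved); this produces a positive
  divergence–effect correlation of modest size ($r^2 \approx 0.06$) —
  deliberately milder than compiled literature tables, where divergence,
  category and cross type are heavily confounded. A category with few
  loci (feeding, $n = 11$) has a volatile sample mean across seeds; its
  permutation p fluctuates accordingly, which is itself faithful to
  small-$n$ meta-analysis.
* `gen_genotypes()` draws SNPs independently (uniform MAF, no linkage
  disequilibrium). Consequently hit sets contain no LD-redundant SNPs
  and the directionality test is never confounded by linkage — passing
  tests here say nothing about LD-driven false directionality in real
  panels.
* `gen_phenotypes()` is strictly additive with Gaussian noise scaled to
  the target $h^2$ from the realized genetic variance. Chain traits are
  built from the parent trait plus (optionally) private genetics — never
  directly from the parent's SNPs — so mediated and forked pleiotropy
  have controlled ground truth.

## Problem sizes and the directionality power ceiling

The parameter-recovery study runs GREML at 1000 lines × 5000 SNPs with 50
causal SNPs, 50 panel replicates, each panel carrying one phenotype per
target $h^2 \in \{0, 0.2, 0.5, 0.8\}$ (a paired design sharing the GRM
eigendecomposition). Calibration checks use 500 replicates at 200
permutations each; GWAS null calibration uses 5000-SNP scans.

The directionality demonstration uses 500 inbred lines × 600 SNPs, 40
causal SNPs per trait with a geometric effect-size spectrum (8-fold range),
$h^2 = 0.97$, chain coefficient 0.8, and a scan threshold of $2 \times
10^{-3}$. On a 600-SNP genome that threshold expects ~1.2 false
associations per scan — comparable (per genome scanned) to the
conventional $5 \times 10^{-6}$ on multimillion-SNP panels, which is the
appropriate way to transfer the convention to a small simulated genome.

These sizes expose a structural ceiling worth knowing about. Detection at
$\alpha = 0.05$ requires roughly $|x_{cor} - y_{cor}| >
1.96\sqrt{1/(|s_1|-1) + 1/(|s_2|-1)}$, so both hit sets must be long; but
a SNP only enters a hit set if its share of trait variance exceeds
$t^2_{thr}/n$, and the shares sum to at most 1, which simultaneously caps
the number of significant SNPs and the effect-size spread that drives
$x_{cor}$ upward. At 500 lines the achievable operating point is
$x_{cor} \approx 0.75$ with hit sets of ~20, giving ~60–75% detection of
chain pairs; the same procedure reaches essentially 100% at 1500 lines.
Forked pairs are flagged at well under the nominal 5% in either case (the
test is conservative there, because symmetric strong cross-correlations
push $D$ toward 1). The acceptance script reports chain power at both
panel sizes.

## Numerical conventions and edge cases

* Spearman correlations are computed as Pearson on midranks with
  round-off within $10^{-12}$ of $\pm 1$ snapped to $\pm 1$, so perfectly
  concordant vectors give exact analytic $D$ values; pairs with fewer
  than three complete observations, or a constant vector, are undefined
  and raise classed errors rather than propagating NaN.
* All stochastic operations take an integer seed and restore the
  caller's RNG state; identical seeds give bit-identical outputs, and
  every pipeline artifact embeds its seed and thresholds.
* Strict inequalities throughout: significance thresholds, the MAF
  filter, the PVE < 20 fraction, heritability screening, and the
  permutation counting rules all exclude boundary values, each documented
  at the function.
* Positions are 1-based (bim/VCF convention). The plink bed codec is
  implemented at the bit level (low-to-high 2-bit codes per byte,
  SNP-major) and round-trips bit-exactly, with dosage counting the
  A1-labelled allele; `-9`/`NA` are accepted as missing phenotype codes.

## Limitations

Beyond the simulator gaps above: no bivariate GREML or genetic
correlations, no dominance/epistasis or X-chromosome model, no
relatedness-corrected association, no LD pruning, and no causal claims
from the directionality test — it discriminates two pleiotropy patterns
under independence assumptions that real linkage disequilibrium violates.
The compiled-table arm treats categories as given; classifying free-text
trait descriptions into categories is curation, not computation, and is
out of scope.
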