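# Shared fixture builders. Everything is generated in code; no data files.

with_seed_test <- function(seed, expr) behavarch:::with_seed(seed, expr)

# Minimal QTL table with full control over the fields the tests exercise.
toy_qtl_table <- function(pve,
                          category = rep("a", length(pve)),
                          study = rep("s1", length(pve)),
                          sample_size = rep(100L, length(pve)),
                          generations = rep(1e5, length(pve)),
                          years = rep(1e5, length(pve)),
                          cross_type = rep("intraspecific", length(pve))) {
  n <- length(pve)
  tab <- data.frame(
    study_id = study, species_a = rep("sp1", n),
    species_b = ifelse(cross_type == "interspecific", "sp2", "sp1"),
    taxon_class = rep("insect", n), behavioral_category = category,
    trait_name = sprintf("t%d", seq_len(n)), effect_size_pve = pve,
    lod = rep(5, n), neglog10_p = rep(NA_real_, n),
    sample_size = sample_size,
    generations_diverged = generations, years_diverged = years,
    cross_type = cross_type, chrom = rep("chr1", n), pos = seq_len(n),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("qtl_table", "data.frame")
  tab
}

# Hand-rolled genotype panel from an explicit dosage matrix.
toy_panel <- function(X, line_ids = NULL, snp_ids = NULL) {
  n <- nrow(X); m <- ncol(X)
  if (is.null(line_ids)) line_ids <- sprintf("L%02d", seq_len(n))
  if (is.null(snp_ids)) snp_ids <- sprintf("S%03d", seq_len(m))
  rownames(X) <- line_ids
  colnames(X) <- snp_ids
  structure(list(line_ids = line_ids,
                 snps = data.frame(id = snp_ids, chrom = "2L",
                                   pos = seq_len(m), a1 = "A", a2 = "T",
                                   stringsAsFactors = FALSE),
                 X = X, freq = colMeans(X, na.rm = TRUE) / 2),
            class = "genotype_panel")
}

# Independent Kruskal-Wallis H for two groups, from first principles
# (midranks + the tie-corrected H formula); used as the enumeration oracle.
oracle_kw_h <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n <- length(pooled)
  groups <- list(seq_along(x), length(x) + seq_along(y))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(groups, function(g) sum(r[g])^2 / length(g), numeric(1))) -
    3 * (n + 1)
  ties <- table(pooled)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# Exact permutation p for the two-group rank test by brute force.
oracle_exact_rank_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); n1 <- length(x)
  h_obs <- oracle_kw_h(x, y)
  combos <- combn(n, n1)
  h_all <- apply(combos, 2L, function(ix) {
    oracle_kw_h(pooled[ix], pooled[-ix])
  })
  mean(h_all >= h_obs - 1e-12)
}

# Spearman rho via explicit midranks + the Pearson formula (oracle).
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Find a permutation of 1:5 whose Spearman correlation with 1:5 equals rho
# exactly (exhaustive search; used to build vectors with exact rank
# correlations).
perm_with_spearman <- function(rho, n = 5L) {
  perms <- behavarch:::all_permutations(n)
  for (i in seq_len(nrow(perms))) {
    if (isTRUE(all.equal(oracle_spearman(seq_len(n), perms[i, ]), rho))) {
      return(perms[i, ])
    }
  }
  stop("no permutation with that exact Spearman correlation")
}

# Frozen chain / fork trait architectures used by the directionality power
# and specificity studies (the package's demonstration conditions).
demo_betas <- function(k, base, ratio = 8) base * ratio^(seq(0, 1, length.out = k))

demo_pair_config <- function(type, seed, n_lines = 500L, n_snps = 600L,
                             k = 40L) {
  bp <- demo_betas(k, 2.0)
  bo <- demo_betas(k, 2.2)
  traits <- switch(type,
    chain = list(trait_spec("p1", causal_snps = 1:k, beta = bp, h2 = 0.97),
                 trait_spec("p2", parent = "p1", chain_coef = 0.8,
                            causal_snps = 301:(300 + k), beta = bo,
                            h2 = 0.97)),
    fork = list(trait_spec("p1", causal_snps = 1:k, beta = bp, h2 = 0.97),
                trait_spec("p2", causal_snps = 1:k, beta = bp, h2 = 0.97)),
    nullfork = list(trait_spec("p1", causal_snps = 1:k, beta = bp, h2 = 0.97),
                    trait_spec("p2", causal_snps = 301:(300 + k), beta = bo,
                               h2 = 0.97)))
  panel_sim_config(n_lines = n_lines, n_snps = n_snps, seed = seed,
                   traits = traits)
}

# Run one simulated trait pair through scan -> hits -> effect matrix ->
# permutation test. Returns NULL when either trait fails the >3-SNP screen.
demo_pair_test <- function(type, seed, n_lines = 500L, threshold = 2e-3,
                           n_perm = 400L) {
  pc <- demo_pair_config(type, seed, n_lines = n_lines)
  panel <- gen_genotypes(pc)
  phen <- gen_phenotypes(panel, pc)
  scans <- list(p1 = assoc_scan(panel, setNames(phen$p1, phen$line_id)),
                p2 = assoc_scan(panel, setNames(phen$p2, phen$line_id)))
  hits <- lapply(scans, significant_hits, threshold = threshold)
  if (length(hits$p1) <= 3L || length(hits$p2) <= 3L) return(NULL)
  em <- build_effect_matrix(scans, hits)
  pv <- pair_vectors(em, "p1", "p2")
  res <- permutation_p(pv$xx, pv$xy, pv$yy, pv$yx, n_perm = n_perm,
                       seed = seed)
  res$screened <- screen_pair(res$x_cor, res$y_cor)
  res
}
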