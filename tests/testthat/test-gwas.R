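test_that("association scan matches the closed-form simple regression", {
  # 6-line toy against explicit least-squares arithmetic
  x <- c(0, 0, 1, 1, 2, 2)
  y <- c(1, 2, 2, 3, 3, 5)
  panel <- toy_panel(cbind(x, matrix(c(0, 2, 0, 2, 0, 2), ncol = 1)))
  res <- assoc_scan(panel, setNames(y, panel$line_ids))
  beta_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(res$beta[1], beta_hand, tolerance = 1e-12)

  # full agreement with lm() on a random panel with missing dosages
  X <- with_seed_test(5, matrix(rbinom(40 * 25, 2, 0.4), 40, 25))
  X[with_seed_test(6, sample(length(X), 30))] <- NA
  yy <- with_seed_test(7, rnorm(40, sd = 2) + 0.3 * ifelse(is.na(X[, 1]), 0, X[, 1]))
  panel2 <- toy_panel(X)
  scan <- assoc_scan(panel2, setNames(yy, panel2$line_ids))
  for (j in c(1, 7, 19)) {
    ok <- !is.na(X[, j])
    fit <- lm(yy[ok] ~ X[ok, j])
    sm <- summary(fit)$coefficients
    expect_equal(scan$beta[j], unname(sm[2, 1]), tolerance = 1e-10)
    expect_equal(scan$se[j], unname(sm[2, 2]), tolerance = 1e-10)
    expect_equal(scan$p[j], unname(sm[2, 4]), tolerance = 1e-10)
    expect_identical(scan$n[j], as.integer(sum(ok)))
  }
})

test_that("exact fits and untestable SNPs are handled", {
  X <- cbind(c(0, 0, 1, 1, 2, 2), rep(2, 6))
  panel <- toy_panel(X)
  y <- 2 * X[, 1]
  res <- assoc_scan(panel, setNames(y, panel$line_ids))
  expect_equal(res$beta[1], 2)
  expect_lt(res$p[1], 1e-10)
  expect_gt(res$p[1], 0)           # clamped, never exactly zero
  expect_false(res$testable[2])     # constant dosage
  expect_true(is.na(res$beta[2]))

  expect_error(assoc_scan(panel, setNames(c(1, 2, rep(NA, 4)), panel$line_ids)),
               class = "behavarch_insufficient_data")
})

test_that("significance filtering is strict at the threshold", {
  res <- structure(data.frame(snp = c("a", "b", "c"), chrom = "1", pos = 1:3,
                              beta = 1, se = 1, stat = 1,
                              p = c(5e-6, 4.9e-6, 0.5), n = 10L,
                              testable = TRUE),
                   class = c("assoc_result", "data.frame"))
  expect_identical(significant_hits(res), "b")
  res$p <- rep(0.5, 3)
  expect_identical(significant_hits(res), character(0))
})

test_that("null GWAS p-values are uniform and hit rates nominal", {
  cfg <- panel_sim_config(n_lines = 300, n_snps = 5000, seed = 81)
  panel <- gen_genotypes(cfg)
  y <- with_seed_test(82, rnorm(300))
  scan <- assoc_scan(panel, setNames(y, panel$line_ids))
  ks <- suppressWarnings(ks.test(scan$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(scan$p < 0.01), 0.02)
})

test_that("power on strong causal SNPs", {
  cfg <- panel_sim_config(n_lines = 1000, n_snps = 1000, seed = 91,
                          traits = list(trait_spec("t", 1:10, beta = 2,
                                                   h2 = 0.6)))
  panel <- gen_genotypes(cfg)
  phen <- gen_phenotypes(panel, cfg)
  hits <- significant_hits(assoc_scan(panel, setNames(phen$t, phen$line_id)))
  expect_gte(sum(panel$snps$id[1:10] %in% hits), 8)
})

test_that("pleiotropy matrix keeps only multi-trait SNPs and maps genes", {
  hits <- list(t1 = c("a", "b", "c", "x"), t2 = c("a", "b", "c", "y"),
               t3 = "z")
  pm <- build_pleiotropy_matrix(hits)
  expect_identical(rownames(pm$incidence), c("a", "b", "c"))
  expect_true(all(rowSums(pm$incidence) == 2))
  expect_identical(unname(pm$snp_trait_counts), rep(2, 3))

  ann <- data.frame(snp = c("a", "b", "c", "x"),
                    gene = c("g1", "g1", "g2", "g3"))
  pm2 <- build_pleiotropy_matrix(hits, annotation = ann)
  expect_identical(pm2$genes$gene, "g1")
  expect_identical(pm2$genes$n_multi_trait_snps, 2L)

  disjoint <- build_pleiotropy_matrix(list(t1 = c("a", "b"), t2 = c("c", "d")))
  expect_identical(nrow(disjoint$incidence), 0L)
  expect_warning(build_pleiotropy_matrix(hits, annotation = data.frame(
    snp = "qqq", gene = "g9")), "no annotation")
  expect_error(build_pleiotropy_matrix(hits["t1"]),
               class = "behavarch_config_error")
})

test_that("effect matrix slices equal the underlying scans", {
  cfg <- panel_sim_config(n_lines = 200, n_snps = 300, seed = 101,
                          traits = list(
                            trait_spec("t1", 1:8, beta = 3, h2 = 0.8),
                            trait_spec("t2", 5:12, beta = 3, h2 = 0.8)))
  panel <- gen_genotypes(cfg)
  phen <- gen_phenotypes(panel, cfg)
  scans <- list(t1 = assoc_scan(panel, setNames(phen$t1, phen$line_id)),
                t2 = assoc_scan(panel, setNames(phen$t2, phen$line_id)))
  hits <- lapply(scans, significant_hits, threshold = 1e-3)
  em <- build_effect_matrix(scans, hits)
  expect_identical(sort(rownames(em)), sort(unique(unlist(hits))))
  for (tr in c("t1", "t2")) {
    ix <- match(rownames(em), scans[[tr]]$snp)
    expect_identical(unname(em[, tr]), scans[[tr]]$beta[ix])
  }

  # single trait, and identical scans give identical columns
  em1 <- build_effect_matrix(scans["t1"], hits["t1"])
  expect_identical(dim(em1), c(length(hits$t1), 1L))
  em2 <- build_effect_matrix(list(a = scans$t1, b = scans$t1),
                             list(a = hits$t1, b = hits$t1))
  expect_identical(em2[, "a"], em2[, "b"])
  expect_error(build_effect_matrix(scans["t1"], hits),
               class = "behavarch_config_error")
})

test_that("trait correlation structure is Spearman with guarded sparsity", {
  m <- cbind(a = c(1, 4, 2, 8, 5), b = c(2, 8, 4, 16, 10))
  rho <- trait_correlation_structure(m)
  expect_equal(rho["a", "b"], 1)
  rho2 <- trait_correlation_structure(cbind(a = m[, 1], b = -m[, 1]))
  expect_equal(rho2["a", "b"], -1)

  # 5-row toy vs midrank Pearson oracle
  m3 <- cbind(a = c(3, 1, 4, 1, 5), b = c(2, 7, 1, 8, 2))
  rho3 <- trait_correlation_structure(m3)
  expect_equal(rho3["a", "b"], oracle_spearman(m3[, "a"], m3[, "b"]))

  # monotone transform invariance
  rho4 <- trait_correlation_structure(cbind(a = exp(m3[, "a"]), b = m3[, "b"]))
  expect_equal(rho4["a", "b"], rho3["a", "b"])

  # pairs with < 3 complete rows are undefined
  m5 <- cbind(a = c(1, 2, NA, NA, NA), b = c(2, 1, NA, NA, NA),
              c = c(1, 2, 3, 4, 5))
  rho5 <- trait_correlation_structure(m5)
  expect_true(is.na(rho5["a", "b"]))
  expect_identical(diag(rho5), c(a = 1, b = 1, c = 1))
})

test_that("sample-size/p-value diagnostic flags degenerate input", {
  sc <- function(n) structure(
    data.frame(snp = c("a", "b", "c", "d"), chrom = "1", pos = 1:4, beta = 1,
               se = 1, stat = 1, p = c(1e-7, 2e-7, 3e-7, 0.5), n = n,
               testable = TRUE),
    class = c("assoc_result", "data.frame"))
  scans <- list(t1 = sc(100L), t2 = sc(100L))
  hits <- list(t1 = c("a", "b", "c"), t2 = c("a", "b", "c"))
  flat <- samplesize_pvalue_correlation(scans, hits)
  expect_false(flat$defined)
  expect_true(is.na(flat$rho))

  scans2 <- list(t1 = sc(100L), t2 = sc(250L))
  ok <- samplesize_pvalue_correlation(scans2, hits)
  expect_true(ok$defined)
  expect_true(abs(ok$rho) <= 1)
})
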