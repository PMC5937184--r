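test_that("LOD to -log10 p conversion matches the chi-square equivalence", {
  expect_identical(lod_to_neglog10p(0), 0)
  # frozen from the 1-df chi-square survival function at 2*ln(10)*3 = 13.8155
  expect_equal(lod_to_neglog10p(3), 3.695371, tolerance = 1e-6)
  expect_gt(lod_to_neglog10p(6), lod_to_neglog10p(3))
  # strictly increasing over a grid, no underflow at large LOD
  lods <- c(0.1, 0.5, 1, 2, 5, 10, 50, 200)
  expect_true(all(diff(lod_to_neglog10p(lods)) > 0))
  expect_true(is.finite(lod_to_neglog10p(200)))
  expect_error(lod_to_neglog10p(-1), class = "behavarch_domain_error")
})

test_that("category summaries report means, medians and the PVE<20 fraction", {
  expect_error(summarize_by_category(toy_qtl_table(numeric(0))),
               class = "behavarch_empty_input")

  one <- summarize_by_category(toy_qtl_table(10))
  expect_equal(one$mean_pve[one$category == "(all)"], 10)
  expect_equal(one$fraction_pve_below_20[one$category == "(all)"], 1)

  two <- summarize_by_category(toy_qtl_table(c(10, 30)))
  glob <- two[two$category == "(all)", ]
  expect_equal(glob$mean_pve, 20)
  expect_equal(glob$fraction_pve_below_20, 0.5)
  expect_equal(glob$median_pve, 20)

  # boundary: the fraction uses strict <
  expect_equal(summarize_by_category(toy_qtl_table(20))$fraction_pve_below_20[1], 0)
})

test_that("category-vs-rest rank test matches kruskal.test and the exact oracle", {
  tab <- toy_qtl_table(c(1, 2, 3, 4, 5, 6),
                       category = rep(c("a", "b"), each = 3))
  res <- category_vs_rest_test(tab, "a")
  kw <- kruskal.test(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$statistic, unname(kw$statistic))
  expect_equal(res$p_value, kw$p.value)

  # exact enumeration agrees with the brute-force oracle (20 arrangements)
  exact <- category_vs_rest_test(tab, "a", exact = TRUE)
  expect_equal(exact$p_value, oracle_exact_rank_p(1:3, 4:6))
  expect_equal(exact$p_value, 2 / 20)

  # exact path with ties, larger groups, against the same oracle
  tab2 <- toy_qtl_table(c(5, 7, 7, 9, 2, 2, 4, 8, 6, 1),
                        category = rep(c("a", "b"), each = 5))
  exact2 <- category_vs_rest_test(tab2, "a", exact = TRUE)
  expect_equal(exact2$p_value,
               oracle_exact_rank_p(c(5, 7, 7, 9, 2), c(2, 4, 8, 6, 1)))

  # identical pooled values: no rank information
  same <- category_vs_rest_test(toy_qtl_table(rep(4, 6),
                                              category = rep(c("a", "b"), 3)),
                                "a")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(category_vs_rest_test(tab, "zzz"),
               class = "behavarch_lookup_error")
  expect_error(category_vs_rest_test(toy_qtl_table(1:3), "a"),
               class = "behavarch_insufficient_data")
})

test_that("cross-type rank test mirrors the category test", {
  tab <- toy_qtl_table(c(1, 2, 3, 10, 11, 12),
                       cross_type = rep(c("intraspecific", "interspecific"),
                                        each = 3))
  res <- cross_type_test(tab, exact = TRUE)
  expect_equal(res$p_value, oracle_exact_rank_p(c(10, 11, 12), c(1, 2, 3)))
  expect_error(cross_type_test(toy_qtl_table(1:4)),
               class = "behavarch_insufficient_data")
})

test_that("permutation category test follows the literal counting rule", {
  # category strictly above every complement value -> p = 0
  tab <- toy_qtl_table(c(50, 60, 1, 2, 3, 4), category = c("a", "a", rep("b", 4)))
  res <- permutation_category_test(tab, "a", n_perm = 500, seed = 1)
  expect_equal(res$p_value, 0)
  expect_equal(res$observed_mean, 55)
  expect_equal(res$n_permutations, 500L)

  # category {9} vs complement {1, 5, 13}: null means are the three values,
  # each equally likely; p -> P(draw = 13) = 1/3
  tab2 <- toy_qtl_table(c(9, 1, 5, 13), category = c("a", "b", "b", "b"))
  res2 <- permutation_category_test(tab2, "a", n_perm = 6000, seed = 2)
  expect_lt(abs(res2$p_value - 1 / 3), 0.03)

  # determinism and the +1 variant
  res3 <- permutation_category_test(tab2, "a", n_perm = 100, seed = 9)
  expect_identical(res3$p_value,
                   permutation_category_test(tab2, "a", n_perm = 100,
                                             seed = 9)$p_value)
  res4 <- permutation_category_test(tab2, "a", n_perm = 100, seed = 9,
                                    plus_one = TRUE)
  expect_equal(res4$p_value, (res3$p_value * 100 + 1) / 101)

  # complement smaller than the category
  tab3 <- toy_qtl_table(c(1, 2, 3, 4), category = c("a", "a", "a", "b"))
  expect_error(permutation_category_test(tab3, "a"),
               class = "behavarch_insufficient_data")
})

test_that("permutation category p-values are uniform under label exchange", {
  # property check: random labels => p ~ U(0,1) up to permutation
  # discreteness; type-I error at alpha = 0.05 within the binomial CI
  n_rep <- 200
  ps <- vapply(seq_len(n_rep), function(i) {
    pve <- with_seed_test(i, rexp(120, 1 / 8))
    lab <- with_seed_test(i + 1e6, sample(rep(c("a", "b"), c(20, 100))))
    permutation_category_test(toy_qtl_table(pve, category = lab), "a",
                              n_perm = 200, seed = i)$p_value
  }, numeric(1))
  rate <- mean(ps < 0.05)
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), ci_half + 0.02)
})

test_that("divergence correlation is Pearson on log10(years)", {
  # exactly linear in log10(years) -> r = 1
  yrs <- 10^seq(4, 8, length.out = 6)
  tab <- toy_qtl_table(seq(2, 12, length.out = 6), years = yrs)
  res <- divergence_effect_correlation(tab)
  expect_equal(res$r, 1)
  expect_equal(res$r_squared, 1)

  # 4-point toy vs the closed-form Pearson formula
  yrs2 <- c(1e4, 1e5, 1e6, 1e7)
  pve2 <- c(3, 7, 6, 12)
  x <- log10(yrs2)
  r_hand <- sum((x - mean(x)) * (pve2 - mean(pve2))) /
    sqrt(sum((x - mean(x))^2) * sum((pve2 - mean(pve2))^2))
  res2 <- divergence_effect_correlation(toy_qtl_table(pve2, years = yrs2))
  expect_equal(res2$r, r_hand)
  expect_equal(res2$r_squared, r_hand^2)

  expect_error(divergence_effect_correlation(toy_qtl_table(1:3, years = rep(0, 3))),
               class = "behavarch_domain_error")
  expect_error(divergence_effect_correlation(toy_qtl_table(1:3, years = rep(1e5, 3))),
               class = "behavarch_degenerate_input")
})

test_that("frequentist LMM reduces to OLS and recovers simulated shifts", {
  tab <- gen_qtl_table(qtl_sim_config(seed = 21))

  # no random effects -> ordinary least squares
  fit0 <- fit_lmm_effects(tab, random = NULL)
  ols <- lm(effect_size_pve ~ behavioral_category,
            data = transform(tab, behavioral_category = factor(behavioral_category)))
  expect_equal(setNames(fit0$fixed_effects$estimate, fit0$fixed_effects$term),
               coef(ols), tolerance = 1e-12)
  expect_true(fit0$converged)

  # parameter recovery: known category shift of 10 on a simulated table
  cfg <- qtl_sim_config(categories = c("base", "shifted"),
                        n_loci_per_category = 500L, mean_pve = c(8, 18),
                        divergence_effect_slope = 0, seed = 8)
  sim <- gen_qtl_table(cfg)
  fit <- fit_lmm_effects(sim, reference = "base")
  row <- fit$fixed_effects[grepl("shifted", fit$fixed_effects$term), ]
  expect_lt(abs(row$estimate - 10), 2 * row$se)
  expect_lt(row$p_value, 1e-6)
  expect_true(is.finite(fit$loglik))
  expect_error(fit_lmm_effects(toy_qtl_table(1:5)),
               class = "behavarch_insufficient_data")
})
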