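test_that("D statistic hits its analytic values exactly", {
  base <- 1:5
  p02 <- perm_with_spearman(0.2)    # rank correlation exactly 0.2 with 1:5
  pm03 <- perm_with_spearman(-0.3)
  p0 <- perm_with_spearman(0)

  # x_cor = 1, y_cor = 0 -> D = 0
  d <- directionality_D(base, base, base, p0)
  expect_identical(c(d$x_cor, d$y_cor, d$D), c(1, 0, 0))

  # equal correlations -> D = 1 (any shared value)
  d2 <- directionality_D(base, p02, base, p02)
  expect_identical(d2$D, 1)

  # x_cor = 0.2, y_cor = -0.3 -> D = 0.5
  d3 <- directionality_D(base, p02, base, pm03)
  expect_equal(d3$x_cor, 0.2)
  expect_equal(d3$y_cor, -0.3)
  expect_equal(d3$D, 0.5)

  expect_error(directionality_D(1:3, 1:3, 1:3, 1:3),
               class = "behavarch_screened_out")
  expect_error(directionality_D(rep(1, 5), 1:5, 1:5, 1:5),
               class = "behavarch_degenerate_input")
})

test_that("D is invariant under monotone transforms and trait swap", {
  xx <- c(2, 9, 4, 7, 1, 6); xy <- c(1, 8, 3, 9, 2, 4)
  yy <- c(5, 2, 8, 1, 9, 3); yx <- c(4, 4.5, 1, 2, 8, 7)
  d <- directionality_D(xx, xy, yy, yx)
  d_mono <- directionality_D(exp(xx / 2), xy, yy, yx^3)
  expect_equal(d_mono$D, d$D)
  d_swap <- directionality_D(yy, yx, xx, xy)
  expect_equal(d_swap$D, d$D)
  expect_equal(d_swap$x_cor, d$y_cor)
  expect_true(d$D >= 0 && d$D <= 1)
})

test_that("screening uses absolute correlations", {
  expect_true(screen_pair(0.9, 0.05))
  expect_false(screen_pair(0.9, 0.4))
  expect_true(screen_pair(-0.86, 0.05))  # strong negative counts as strong
  expect_true(screen_pair(0.05, -0.7))
  expect_false(screen_pair(0.05, 0.05))
  expect_false(screen_pair(0.51, 0.1))   # low bound is strict
})

test_that("permutation p-value follows the strict counting rule", {
  base <- 1:8
  # yx0 has Spearman correlation exactly 0 with 1:8 (sum d^2 = 84), so the
  # observed D is exactly 0 and no permuted D can fall strictly below it
  yx0 <- c(3, 7, 5, 1, 8, 2, 6, 4)
  res <- permutation_p(base, base, base, yx0, n_perm = 300, seed = 1)
  expect_identical(res$D, 0)
  expect_identical(res$p_value, 0)

  # reproducible given the seed
  expect_identical(
    permutation_p(base, rev(base), base, yx0, n_perm = 250, seed = 7)$p_value,
    permutation_p(base, rev(base), base, yx0, n_perm = 250, seed = 7)$p_value)
})

test_that("exact enumeration fallback matches Monte Carlo on tiny vectors", {
  xx <- 1:4; xy <- c(2, 1, 4, 3); yy <- 1:4; yx <- c(4, 3, 1, 2)
  # 24 * 24 = 576 distinct relative permutations < n_perm triggers exact mode
  expect_warning(ex <- permutation_p(xx, xy, yy, yx, n_perm = 1000, seed = 1),
                 "enumerating exactly")
  expect_true(ex$exact)

  mc <- permutation_p(xx, xy, yy, yx, n_perm = 500, seed = 3)
  expect_false(mc$exact)
  expect_lt(abs(mc$p_value - ex$p_value), 0.08)

  # joint flag induces the same null distribution
  mcj <- permutation_p(xx, xy, yy, yx, n_perm = 500, seed = 3, joint = TRUE)
  expect_lt(abs(mcj$p_value - ex$p_value), 0.08)
})

test_that("pair vectors are exact effect-matrix slices with a strict screen", {
  cfg <- demo_pair_config("nullfork", seed = 9, n_lines = 300)
  panel <- gen_genotypes(cfg)
  phen <- gen_phenotypes(panel, cfg)
  scans <- list(p1 = assoc_scan(panel, setNames(phen$p1, phen$line_id)),
                p2 = assoc_scan(panel, setNames(phen$p2, phen$line_id)))
  hits <- lapply(scans, significant_hits, threshold = 1e-3)
  em <- build_effect_matrix(scans, hits)
  pv <- pair_vectors(em, "p1", "p2")
  expect_identical(unname(pv$xx), unname(em[pv$s1, "p1"]))
  expect_identical(unname(pv$xy), unname(em[pv$s1, "p2"]))
  expect_identical(unname(pv$yy), unname(em[pv$s2, "p2"]))
  expect_identical(length(pv$xx), length(hits$p1))

  # a trait at the 3-hit boundary is screened out
  hits3 <- hits; hits3$p1 <- hits3$p1[1:3]
  expect_error(pair_vectors(em, "p1", "p2", hits3),
               class = "behavarch_screened_out")
  expect_error(pair_vectors(em, "p1", "zzz"),
               class = "behavarch_lookup_error")
})

test_that("Bonferroni adjustment and reporting are arithmetic", {
  pairs <- data.frame(trait_x = c("a", "b"), trait_y = c("b", "c"),
                      n_s1 = 5L, n_s2 = 5L, x_cor = c(0.9, 0.2),
                      y_cor = c(0.05, 0.1), D = c(0.1, 0.9),
                      p_perm = c(0.002, 0.4),
                      passed_screen = c(TRUE, FALSE))
  rep1 <- adjust_and_report(pairs[1, ])
  expect_equal(rep1$p_adjusted, rep1$p_perm)

  rep2 <- adjust_and_report(transform(pairs, p_perm = c(0.02, 0.4)),
                            n_tests = 10)
  expect_equal(rep2$p_adjusted, c(0.2, 1))
  expect_false(any(rep2$significant))

  rep3 <- adjust_and_report(pairs)
  expect_true(rep3$significant[1])
  expect_identical(rep3$trait_x[1], "a")  # sorted by adjusted p
  expect_error(adjust_and_report(pairs[0, ]), class = "behavarch_empty_input")
})

test_that("chain pairs are enriched at the top of the adjusted ranking", {
  # mixed battery: 3 mediated (chain) pairs and 6 exchangeable null pairs
  types <- rep(c("chain", "nullfork"), c(3, 6))
  rows <- Map(function(type, seed) {
    r <- demo_pair_test(type, seed)
    if (is.null(r)) return(NULL)
    data.frame(trait_x = paste0(type, seed), trait_y = "p2",
               n_s1 = 10L, n_s2 = 10L, x_cor = r$x_cor, y_cor = r$y_cor,
               D = r$D, p_perm = r$p_value, passed_screen = r$screened,
               is_chain = type == "chain")
  }, types, 300 + seq_along(types))
  tab <- do.call(rbind, Filter(Negate(is.null), rows))
  rep <- adjust_and_report(tab)
  expect_true(all(rep$p_adjusted >= rep$p_perm))
  rank_chain <- mean(which(rep$is_chain))
  rank_null <- mean(which(!rep$is_chain))
  expect_lt(rank_chain, rank_null)
})
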