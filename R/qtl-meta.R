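#' Convert a LOD score to a -log10 p-value
#'
#' Uses the interval-mapping likelihood-ratio equivalence: a LOD score L
#' corresponds to the LRT statistic 2 ln(10) L, referred to a 1-df
#' chi-square. Computed on the log scale so large LOD scores do not
#' underflow.
#'
#' @param lod nonnegative LOD score(s).
#' @return -log10 of the upper-tail chi-square probability; 0 at LOD 0,
#'   strictly increasing in LOD.
#' @examples
#' lod_to_neglog10p(3) # about 3.70
#' @export
lod_to_neglog10p <- function(lod) {
  if (any(!is.na(lod) & lod < 0)) {
    ba_stop("LOD scores must be nonnegative", class = "behavarch_domain_error")
  }
  -pchisq(2 * log(10) * lod, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
}

check_qtl_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    ba_stop("empty QTL record collection", class = "behavarch_empty_input")
  }
  records
}

#' Summarize QTL effect sizes by behavioral category
#'
#' @param records a `qtl_table` (or compatible data.frame with columns
#'   `behavioral_category` and `effect_size_pve`).
#' @param pve_cutoff PVE threshold for the "fraction below" summary
#'   (strict `<`, default 20).
#' @return A data.frame of class `category_summary`: one row per category
#'   plus a first row `(all)` for the global summary, with columns
#'   `category`, `n_loci`, `mean_pve`, `median_pve`, `fraction_pve_below_20`.
#' @export
summarize_by_category <- function(records, pve_cutoff = 20) {
  check_qtl_records(records)
  pve <- records$effect_size_pve
  one <- function(label, x) {
    data.frame(category = label, n_loci = length(x), mean_pve = mean(x),
               median_pve = median(x),
               fraction_pve_below_20 = mean(x < pve_cutoff),
               stringsAsFactors = FALSE)
  }
  per_cat <- lapply(sort(unique(records$behavioral_category)), function(cat) {
    one(cat, pve[records$behavioral_category == cat])
  })
  out <- do.call(rbind, c(list(one("(all)", pve)), per_cat))
  rownames(out) <- NULL
  class(out) <- c("category_summary", "data.frame")
  out
}

# Two-group Kruskal-Wallis: chi-square approximation via stats::kruskal.test
# or, for small samples, the exact permutation distribution of the H
# statistic over all group assignments.
two_group_rank_test <- function(x, y, exact = FALSE) {
  if (length(x) == 0L || length(y) == 0L) {
    ba_stop("both groups must be nonempty", class = "behavarch_insufficient_data")
  }
  if (length(unique(c(x, y))) == 1L) {
    # all pooled values tied: no rank information, statistic 0 and p = 1
    return(list(statistic = 0, p_value = 1,
                method = "kruskal-wallis degenerate (all values tied)"))
  } else {
    kw <- suppressWarnings(kruskal.test(list(x, y)))
    out <- list(statistic = unname(kw$statistic), p_value = unname(kw$p.value),
                method = "kruskal-wallis chi-square")
  }
  if (exact) {
    pooled <- c(x, y)
    n <- length(pooled); n1 <- length(x)
    if (choose(n, n1) > 2e5) {
      ba_stop("exact enumeration infeasible for these group sizes")
    }
    h_of <- function(idx) {
      suppressWarnings(unname(kruskal.test(list(pooled[idx], pooled[-idx]))$statistic))
    }
    h_obs <- h_of(seq_len(n1))
    combos <- combn(n, n1)
    h_all <- apply(combos, 2L, h_of)
    out$statistic <- h_obs
    out$p_value <- mean(h_all >= h_obs - 1e-12)
    out$method <- "kruskal-wallis exact enumeration"
  }
  out
}

#' Test one behavioral category against all others (rank test)
#'
#' Two-group Kruskal-Wallis (with midrank ties correction) of the category's
#' PVE values against the PVE of every remaining locus. With `exact = TRUE`
#' the p-value is instead the exact permutation tail of the H statistic over
#' all group assignments (feasible for small tables only).
#'
#' @param records a `qtl_table`.
#' @param category category label to test.
#' @param exact use exhaustive enumeration instead of the chi-square
#'   approximation.
#' @return list with `statistic`, `p_value`, `method`, `n_category`,
#'   `n_rest`.
#' @export
category_vs_rest_test <- function(records, category, exact = FALSE) {
  check_qtl_records(records)
  in_cat <- records$behavioral_category == category
  if (!any(in_cat)) {
    ba_stop(sprintf("category '%s' not present", category),
            class = "behavarch_lookup_error")
  }
  if (all(in_cat)) {
    ba_stop("complement is empty", class = "behavarch_insufficient_data")
  }
  res <- two_group_rank_test(records$effect_size_pve[in_cat],
                             records$effect_size_pve[!in_cat], exact = exact)
  res$n_category <- sum(in_cat)
  res$n_rest <- sum(!in_cat)
  res
}

#' Test cross-type (interspecific vs intraspecific) effect-size difference
#'
#' @inheritParams category_vs_rest_test
#' @return as [category_vs_rest_test()].
#' @export
cross_type_test <- function(records, exact = FALSE) {
  check_qtl_records(records)
  inter <- records$cross_type == "interspecific"
  if (!any(inter) || all(inter)) {
    ba_stop("both cross types must be present",
            class = "behavarch_insufficient_data")
  }
  res <- two_group_rank_test(records$effect_size_pve[inter],
                             records$effect_size_pve[!inter], exact = exact)
  res$n_interspecific <- sum(inter)
  res$n_intraspecific <- sum(!inter)
  res
}

#' Permutation test of a category's mean effect size
#'
#' Builds a null distribution for the category mean by drawing, without
#' replacement, samples of the category's size from the complement's PVE
#' values (the "remaining effect sizes") and recording each sample mean.
#' The p-value is the fraction of null means strictly greater than the
#' observed category mean; with `plus_one = TRUE` the small-sample-safe
#' (b + 1)/(B + 1) variant is used instead.
#'
#' @param records a `qtl_table`.
#' @param category category label to test.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed (draws are deterministic given it).
#' @param plus_one use the add-one p-value correction.
#' @return A list of class `permutation_result`: `category`,
#'   `observed_mean`, `n_category`, `n_permutations`, `p_value`,
#'   `null_mean_summary` (mean and quantiles of the null means), `seed`.
#' @export
permutation_category_test <- function(records, category, n_perm = 10000L,
                                      seed = 1L, plus_one = FALSE) {
  check_qtl_records(records)
  if (n_perm < 1L) ba_stop("n_perm must be >= 1", class = "behavarch_config_error")
  in_cat <- records$behavioral_category == category
  if (!any(in_cat)) {
    ba_stop(sprintf("category '%s' not present", category),
            class = "behavarch_lookup_error")
  }
  cat_pve <- records$effect_size_pve[in_cat]
  rest <- records$effect_size_pve[!in_cat]
  n_cat <- length(cat_pve)
  if (length(rest) < n_cat) {
    ba_stop("complement smaller than the category: cannot sample without replacement",
            class = "behavarch_insufficient_data")
  }
  observed <- mean(cat_pve)
  null_means <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) mean(sample(rest, n_cat)), numeric(1))
  })
  exceed <- sum(null_means > observed)
  p <- if (plus_one) (exceed + 1) / (n_perm + 1) else exceed / n_perm
  structure(list(category = category, observed_mean = observed,
                 n_category = n_cat, n_permutations = as.integer(n_perm),
                 p_value = p,
                 null_mean_summary = c(mean = mean(null_means),
                                       quantile(null_means,
                                                c(0.025, 0.5, 0.975))),
                 seed = seed),
            class = "permutation_result")
}

#' Correlation between evolutionary divergence and effect size
#'
#' Pearson correlation of log10(years since divergence) against per-locus
#' PVE.
#'
#' @param records a `qtl_table`; all rows must have `years_diverged > 0`.
#' @return list with `r`, `r_squared`, `p_value`, `n`.
#' @export
divergence_effect_correlation <- function(records) {
  check_qtl_records(records)
  if (any(is.na(records$years_diverged)) || any(records$years_diverged <= 0)) {
    ba_stop("years_diverged must be positive for all records",
            class = "behavarch_domain_error")
  }
  x <- log10(records$years_diverged)
  y <- records$effect_size_pve
  if (sd(x) == 0 || sd(y) == 0) {
    ba_stop("zero variance in divergence or effect size",
            class = "behavarch_degenerate_input")
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, n = length(x))
}
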