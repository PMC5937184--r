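#' Extract the four effect-size vectors for a trait pair
#'
#' For traits x and y, with s1 the SNPs significant for x and s2 those
#' significant for y: `xx`/`xy` are the effect sizes at s1 for x and y, and
#' `yy`/`yx` those at s2 for y and x. Both traits must have strictly more
#' than `min_snps` significant SNPs; a trait at or below the bound is
#' screened out with a classed error (`behavarch_screened_out`).
#'
#' @param em an `effect_matrix` from [build_effect_matrix()].
#' @param hit_sets named list of significant SNP ids per trait (defaults to
#'   the sets stored on the matrix).
#' @param trait_x,trait_y trait (column) names.
#' @param min_snps screening bound; traits need `> min_snps` hits
#'   (default 3).
#' @return list with `xx`, `xy`, `yy`, `yx`, `s1`, `s2`.
#' @export
pair_vectors <- function(em, trait_x, trait_y,
                         hit_sets = attr(em, "hit_sets"), min_snps = 3L) {
  if (is.null(hit_sets)) ba_stop("no hit sets supplied or stored on the matrix",
                                 class = "behavarch_config_error")
  for (tr in c(trait_x, trait_y)) {
    if (!tr %in% colnames(em) || is.null(hit_sets[[tr]])) {
      ba_stop(sprintf("trait '%s' not present", tr),
              class = "behavarch_lookup_error")
    }
  }
  s1 <- intersect(hit_sets[[trait_x]], rownames(em))
  s2 <- intersect(hit_sets[[trait_y]], rownames(em))
  if (length(s1) <= min_snps || length(s2) <= min_snps) {
    ba_stop(sprintf("pair (%s, %s) screened out: needs > %d significant SNPs for both traits",
                    trait_x, trait_y, min_snps),
            class = "behavarch_screened_out")
  }
  list(xx = em[s1, trait_x], xy = em[s1, trait_y],
       yy = em[s2, trait_y], yx = em[s2, trait_x],
       s1 = s1, s2 = s2)
}

#' The trait-pair directionality statistic D
#'
#' Spearman cross-correlations x_cor = rho(xx, xy) and y_cor = rho(yy, yx)
#' on pairwise-complete observations, combined as
#' \deqn{D = |1 - |x\_cor - y\_cor||.}
#' Small D marks an asymmetric pair: the strongest directional signal is
#' |x_cor - y_cor| = 1 (one cross-correlation strong, the other absent),
#' giving D = 0, whereas x_cor = y_cor gives D = 1.
#'
#' @param xx,xy,yy,yx effect-size vectors from [pair_vectors()].
#' @return list with `x_cor`, `y_cor`, `D`.
#' @export
directionality_D <- function(xx, xy, yy, yx) {
  if (length(xx) < 4L || length(yy) < 4L) {
    ba_stop("each SNP set must contribute >= 4 effect sizes",
            class = "behavarch_screened_out")
  }
  x_cor <- spearman_cor(xx, xy)
  y_cor <- spearman_cor(yy, yx)
  if (is.na(x_cor) || is.na(y_cor)) {
    ba_stop("undefined rank correlation (constant vector or too few complete pairs)",
            class = "behavarch_degenerate_input")
  }
  list(x_cor = x_cor, y_cor = y_cor, D = abs(1 - abs(x_cor - y_cor)))
}

#' Screening rule for directional trait pairs
#'
#' A pair passes when one cross-correlation is strong and the other near
#' zero, in absolute value: (|x_cor| > high and |y_cor| < low) or vice
#' versa. Absolute values are used so strong negative correlations count as
#' strong.
#'
#' @param x_cor,y_cor Spearman cross-correlations.
#' @param high,low screening bounds (defaults 0.5 and 0.1).
#' @return logical.
#' @export
screen_pair <- function(x_cor, y_cor, high = 0.5, low = 0.1) {
  (abs(x_cor) > high & abs(y_cor) < low) |
    (abs(y_cor) > high & abs(x_cor) < low)
}

#' Permutation p-value for the directionality statistic
#'
#' Each iteration independently permutes all four effect-size vectors,
#' recomputes the two cross-correlations and D. The p-value is the fraction
#' of iterations whose permuted D lies strictly below the observed D
#' (ties count toward the null), so small observed D gives small p. When
#' the number of distinct permutation outcomes is below `n_perm` the exact
#' permutation distribution is enumerated instead (with a warning); the
#' distribution factorizes over the two correlations, so enumeration needs
#' only n1!^2 + n2!^2 correlation evaluations.
#'
#' @param xx,xy,yy,yx effect-size vectors.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param joint permute only the cross vectors (xy against a fixed xx, yx
#'   against a fixed yy) instead of permuting all four independently. For a
#'   rank correlation the two schemes induce the same null distribution
#'   (only the relative permutation matters); the flag exists to make that
#'   explicit. Default FALSE.
#' @return list with `p_value`, `D`, `x_cor`, `y_cor`, `n_perm`, `exact`.
#' @export
permutation_p <- function(xx, xy, yy, yx, n_perm = 1000L, seed = 1L,
                          joint = FALSE) {
  obs <- directionality_D(xx, xy, yy, yx)
  n1 <- length(xx); n2 <- length(yy)
  n_distinct <- factorial(n1) * factorial(n2)
  if (!joint && n1 <= 6 && n2 <= 6 && n_distinct < n_perm) {
    warning(sprintf("only %d distinct permutations possible; enumerating exactly",
                    n_distinct))
    perm1 <- all_permutations(n1)
    perm2 <- all_permutations(n2)
    xc <- apply(perm1, 1L, function(ix) spearman_cor(xx[ix], xy))
    yc <- apply(perm2, 1L, function(ix) spearman_cor(yy[ix], yx))
    pd <- abs(1 - abs(outer(xc, yc, `-`)))
    p <- mean(obs$D > pd)
    return(list(p_value = p, D = obs$D, x_cor = obs$x_cor, y_cor = obs$y_cor,
                n_perm = length(pd), exact = TRUE))
  }
  pd <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      if (joint) {
        xc <- spearman_cor(xx, sample(xy))
        yc <- spearman_cor(yy, sample(yx))
      } else {
        xc <- spearman_cor(sample(xx), sample(xy))
        yc <- spearman_cor(sample(yy), sample(yx))
      }
      abs(1 - abs(xc - yc))
    }, numeric(1))
  })
  if (anyNA(pd)) ba_stop("undefined correlation in permutation null",
                         class = "behavarch_degenerate_input")
  list(p_value = sum(obs$D > pd) / n_perm, D = obs$D,
       x_cor = obs$x_cor, y_cor = obs$y_cor,
       n_perm = as.integer(n_perm), exact = FALSE)
}

#' Test every eligible trait pair for directionality
#'
#' Runs [pair_vectors()], [directionality_D()], [screen_pair()] and
#' [permutation_p()] over all unordered pairs of traits with more than
#' `min_snps` significant SNPs.
#'
#' @param em an `effect_matrix`.
#' @param hit_sets named list of significant SNP ids (defaults to the sets
#'   stored on the matrix).
#' @param n_perm,seed permutation settings.
#' @param high,low screening bounds (see [screen_pair()]).
#' @param min_snps minimum hit count (strict) per trait.
#' @return data.frame, one row per tested pair: `trait_x`, `trait_y`,
#'   `n_s1`, `n_s2`, `x_cor`, `y_cor`, `D`, `p_perm`, `passed_screen`.
#' @export
test_trait_pairs <- function(em, hit_sets = attr(em, "hit_sets"),
                             n_perm = 1000L, seed = 1L,
                             high = 0.5, low = 0.1, min_snps = 3L) {
  traits <- names(hit_sets)[vapply(hit_sets, function(h) {
    length(intersect(h, rownames(em))) > min_snps
  }, logical(1))]
  if (length(traits) < 2L) {
    ba_stop("fewer than two traits pass the SNP-count screen",
            class = "behavarch_insufficient_data")
  }
  rows <- list()
  k <- 0L
  for (i in seq_len(length(traits) - 1L)) {
    for (j in seq((i + 1L), length(traits))) {
      k <- k + 1L
      pv <- pair_vectors(em, traits[i], traits[j], hit_sets,
                         min_snps = min_snps)
      res <- tryCatch(
        permutation_p(pv$xx, pv$xy, pv$yy, pv$yx, n_perm = n_perm,
                      seed = seed + k),
        behavarch_degenerate_input = function(e) NULL
      )
      if (is.null(res)) next
      rows[[k]] <- data.frame(
        trait_x = traits[i], trait_y = traits[j],
        n_s1 = length(pv$s1), n_s2 = length(pv$s2),
        x_cor = res$x_cor, y_cor = res$y_cor, D = res$D,
        p_perm = res$p_value,
        passed_screen = screen_pair(res$x_cor, res$y_cor, high, low),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    ba_stop("no testable trait pairs", class = "behavarch_insufficient_data")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bonferroni-adjust and rank trait-pair results
#'
#' Multiplies each permutation p-value by the number of pairs actually
#' tested (capped at 1), sorts by adjusted p, and flags the significant
#' directional pairs as those that both reach `alpha` after adjustment and
#' pass the correlation screen.
#'
#' @param pairs data.frame from [test_trait_pairs()] (or a list of
#'   [permutation_p()]-style results with screen flags).
#' @param alpha significance level for the `significant` flag.
#' @param n_tests Bonferroni divisor; defaults to `nrow(pairs)` (the pairs
#'   actually tested).
#' @return The input data.frame of class `trait_pair_table`, sorted by
#'   `p_adjusted`, with columns `p_adjusted` and `significant` added.
#' @export
adjust_and_report <- function(pairs, alpha = 0.05, n_tests = nrow(pairs)) {
  if (!is.data.frame(pairs) || nrow(pairs) < 1L) {
    ba_stop("need >= 1 tested pair", class = "behavarch_empty_input")
  }
  pairs$p_adjusted <- pmin(1, pairs$p_perm * n_tests)
  pairs$significant <- pairs$p_adjusted < alpha & pairs$passed_screen
  pairs <- pairs[order(pairs$p_adjusted, pairs$D), , drop = FALSE]
  rownames(pairs) <- NULL
  class(pairs) <- c("trait_pair_table", "data.frame")
  pairs
}
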