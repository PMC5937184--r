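#' Specify a simulated trait on a genotype panel
#'
#' Traits are additive: y = sum_i beta_i x_i + e, with the environmental
#' variance scaled so the realized genetic fraction of variance matches
#' `h2`. A "chain" trait is generated from a parent trait,
#' y = a * parent + residual: the causal pattern in which the parent's
#' genotypes reach the trait only through the parent. The residual is pure
#' noise (`chain_noise_sd`) or, when the chain trait has its own
#' `causal_snps`, an additive genetic component of its own plus noise scaled
#' to the trait's `h2` — the realistic case in which a downstream trait also
#' has private genetics. "Fork" pleiotropy is obtained by giving two
#' independent traits overlapping `causal_snps`.
#'
#' @param name trait name.
#' @param causal_snps integer indices of causal SNPs in the panel.
#' @param beta effect sizes per causal SNP (recycled).
#' @param h2 target fraction of phenotypic variance that is genetic,
#'   in [0, 1).
#' @param parent for a chain trait, the name of the parent trait.
#' @param chain_coef coefficient `a` of the parent in a chain trait.
#' @param chain_noise_sd standard deviation of chain noise.
#' @return A `trait_spec` list.
#' @export
trait_spec <- function(name, causal_snps = integer(), beta = 1, h2 = 0.5,
                       parent = NULL, chain_coef = 1, chain_noise_sd = 1) {
  if (!is.null(parent)) {
    if (!is.finite(chain_coef)) {
      ba_stop("chain coefficient must be finite", class = "behavarch_config_error")
    }
  } else {
    if (!is.numeric(h2) || length(h2) != 1L || is.na(h2) || h2 < 0 || h2 >= 1) {
      ba_stop("`h2` must lie in [0, 1)", class = "behavarch_config_error")
    }
  }
  structure(list(name = name,
                 causal_snps = as.integer(causal_snps),
                 beta = rep_len(as.numeric(beta), length(causal_snps)),
                 h2 = h2, parent = parent,
                 chain_coef = chain_coef, chain_noise_sd = chain_noise_sd),
            class = "trait_spec")
}

#' Configuration for the synthetic inbred-line genotype/phenotype panel
#'
#' Emulates a panel of fully inbred, fully genotyped lines (a DGRP-style
#' mapping resource): biallelic SNPs drawn independently with minor allele
#' frequencies uniform on `maf_range`, dosages in \{0, 2\} for inbred lines
#' (\{0, 1, 2\} Hardy-Weinberg otherwise), and additive traits described by
#' [trait_spec()].
#'
#' @param n_lines number of lines (>= 2).
#' @param n_snps number of SNPs (>= 1).
#' @param maf_range minor-allele-frequency bounds, within (0, 0.5].
#' @param inbred if TRUE (default) dosages are restricted to \{0, 2\}.
#' @param traits list of [trait_spec()] objects.
#' @param seed integer seed.
#' @return An object of class `panel_sim_config`.
#' @export
panel_sim_config <- function(n_lines = 200L, n_snps = 5000L,
                             maf_range = c(0.05, 0.5), inbred = TRUE,
                             traits = list(), seed = 1L) {
  n_lines <- as.integer(n_lines); n_snps <- as.integer(n_snps)
  if (n_lines < 2L) ba_stop("n_lines must be >= 2", class = "behavarch_config_error")
  if (n_snps < 1L) ba_stop("n_snps must be >= 1", class = "behavarch_config_error")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[2] < maf_range[1]) {
    ba_stop("maf_range must lie within (0, 0.5]", class = "behavarch_config_error")
  }
  for (tr in traits) {
    if (!inherits(tr, "trait_spec")) {
      ba_stop("every trait must be a trait_spec", class = "behavarch_config_error")
    }
    if (length(tr$causal_snps) && any(tr$causal_snps < 1L | tr$causal_snps > n_snps)) {
      ba_stop(sprintf("trait '%s' has causal SNP indices outside the panel", tr$name),
              class = "behavarch_config_error")
    }
  }
  structure(list(n_lines = n_lines, n_snps = n_snps, maf_range = maf_range,
                 inbred = isTRUE(inbred), traits = traits,
                 seed = as.integer(seed)),
            class = "panel_sim_config")
}

#' Generate a synthetic genotype panel
#'
#' @param config a [panel_sim_config()].
#' @return A `genotype_panel`: list with `line_ids`, `snps` (data.frame with
#'   `id`, `chrom`, `pos`, `a1`, `a2`), dosage matrix `X` (lines x SNPs,
#'   counts of the a1 allele), and per-SNP allele frequency `freq`
#'   (frequency of a1 on non-missing calls). Seed stored in the `seed`
#'   element.
#' @export
gen_genotypes <- function(config) {
  if (!inherits(config, "panel_sim_config")) {
    ba_stop("`config` must be a panel_sim_config", class = "behavarch_config_error")
  }
  with_seed(config$seed, {
    n <- config$n_lines; m <- config$n_snps
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    X <- if (config$inbred) {
      matrix(rbinom(n * m, 1L, rep(maf, each = n)) * 2L, n, m)
    } else {
      matrix(rbinom(n * m, 2L, rep(maf, each = n)), n, m)
    }
    line_ids <- sprintf("line_%04d", seq_len(n))
    snps <- data.frame(
      id = sprintf("snp_%06d", seq_len(m)),
      chrom = sample(c("2L", "2R", "3L", "3R", "4"), m, replace = TRUE),
      pos = sample.int(3e7L, m, replace = TRUE),
      a1 = "A", a2 = "T",
      stringsAsFactors = FALSE
    )
    rownames(X) <- line_ids
    colnames(X) <- snps$id
    new_genotype_panel(line_ids, snps, X, seed = config$seed,
                       drawn_maf = maf)
  })
}

new_genotype_panel <- function(line_ids, snps, X, seed = NULL,
                               drawn_maf = NULL) {
  structure(list(line_ids = line_ids, snps = snps, X = X,
                 freq = colMeans(X, na.rm = TRUE) / 2,
                 seed = seed, drawn_maf = drawn_maf),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d lines x %d SNPs\n",
              length(x$line_ids), nrow(x$snps)))
  invisible(x)
}

#' Generate phenotypes on a genotype panel
#'
#' Additive traits are built as y = X[, causal] %*% beta + e with e Gaussian,
#' its variance set from the realized genetic variance so that
#' Vg / (Vg + Ve) equals the trait's target h2 (h2 = 0 gives pure noise).
#' Chain traits are built from their parent trait only, never directly from
#' genotype.
#'
#' @param panel a `genotype_panel`.
#' @param config the [panel_sim_config()] whose `traits` to realize.
#' @param seed optional seed overriding `config$seed + 1`.
#' @return A data.frame of class `phenotype_table`: `line_id` plus one
#'   column per trait. Realized genetic values are stored in
#'   `attr(, "genetic_values")` and the seed in `attr(, "seed")`.
#' @export
gen_phenotypes <- function(panel, config, seed = NULL) {
  if (!inherits(panel, "genotype_panel")) ba_stop("`panel` must be a genotype_panel")
  if (length(config$traits) == 0L) ba_stop("no traits configured",
                                           class = "behavarch_config_error")
  if (is.null(seed)) seed <- config$seed + 1L
  with_seed(seed, {
    n <- length(panel$line_ids)
    out <- data.frame(line_id = panel$line_ids, stringsAsFactors = FALSE)
    gvals <- list()
    for (tr in config$traits) {
      if (is.null(tr$parent)) {
        g <- if (length(tr$causal_snps)) {
          as.numeric(panel$X[, tr$causal_snps, drop = FALSE] %*% tr$beta)
        } else rep(0, n)
        vg <- var(g)
        if (tr$h2 == 0 || vg == 0) {
          y <- g * 0 + rnorm(n, sd = 1)
          if (tr$h2 > 0 && vg == 0) {
            warning(sprintf("trait '%s': zero realized genetic variance", tr$name))
          }
        } else {
          ve <- vg * (1 - tr$h2) / tr$h2
          y <- g + rnorm(n, sd = sqrt(ve))
        }
        gvals[[tr$name]] <- g
      } else {
        if (is.null(out[[tr$parent]])) {
          ba_stop(sprintf("chain trait '%s' refers to unknown parent '%s' (order matters)",
                          tr$name, tr$parent), class = "behavarch_config_error")
        }
        if (length(tr$causal_snps)) {
          g_own <- as.numeric(panel$X[, tr$causal_snps, drop = FALSE] %*% tr$beta)
          vg <- var(g_own)
          resid <- if (tr$h2 > 0 && vg > 0) {
            g_own + rnorm(n, sd = sqrt(vg * (1 - tr$h2) / tr$h2))
          } else {
            rnorm(n, sd = if (tr$chain_noise_sd > 0) tr$chain_noise_sd else 1)
          }
        } else {
          g_own <- rep(0, n)
          resid <- if (tr$chain_noise_sd > 0) rnorm(n, sd = tr$chain_noise_sd) else 0
        }
        y <- tr$chain_coef * out[[tr$parent]] + resid
        gvals[[tr$name]] <- tr$chain_coef * gvals[[tr$parent]] + g_own
      }
      out[[tr$name]] <- y
    }
    class(out) <- c("phenotype_table", "data.frame")
    attr(out, "genetic_values") <- gvals
    attr(out, "seed") <- seed
    out
  })
}
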