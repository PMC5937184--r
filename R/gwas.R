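#' Single-SNP association scan for one quantitative trait
#'
#' Per SNP, simple linear regression of the phenotype on allele dosage
#' (intercept + dosage): beta = Sxy/Sxx, SE from the residual variance,
#' two-sided t test on n - 2 df. Lines with a missing phenotype are dropped
#' globally; lines with a missing dosage are dropped per SNP. SNPs with no
#' dosage variance among the tested lines are returned with
#' `testable = FALSE` rather than aborting the scan. The whole scan is
#' vectorized over SNPs.
#'
#' @param panel a `genotype_panel`.
#' @param phenotype per-line values, aligned with `panel$line_ids` or named
#'   by line id.
#' @return data.frame of class `assoc_result` with columns `snp`, `chrom`,
#'   `pos`, `beta`, `se`, `stat`, `p`, `n`, `testable` (qassoc-style
#'   ordering).
#' @export
assoc_scan <- function(panel, phenotype) {
  if (!inherits(panel, "genotype_panel")) ba_stop("`panel` must be a genotype_panel")
  y <- align_phenotype(panel$line_ids, phenotype)
  ok <- !is.na(y)
  if (sum(ok) < 3L) {
    ba_stop("need >= 3 lines with non-missing phenotype",
            class = "behavarch_insufficient_data")
  }
  X <- panel$X[ok, , drop = FALSE]
  y <- y[ok]
  O <- !is.na(X)
  Xz <- X; Xz[!O] <- 0
  n <- colSums(O)
  sx <- colSums(Xz)
  sxx <- colSums(Xz * Xz)
  sxy <- as.numeric(crossprod(Xz, y))
  sy <- as.numeric(crossprod(O, y))
  syy <- as.numeric(crossprod(O, y * y))
  Sxx <- sxx - sx^2 / n
  Sxy <- sxy - sx * sy / n
  Syy <- syy - sy^2 / n
  testable <- n >= 3L & Sxx > 1e-12
  beta <- ifelse(testable, Sxy / Sxx, NA_real_)
  rss <- pmax(0, Syy - beta^2 * Sxx)
  sigma2 <- rss / (n - 2)
  se <- ifelse(testable, sqrt(sigma2 / Sxx), NA_real_)
  stat <- ifelse(testable & se > 0, beta / se,
                 ifelse(testable, sign(beta) * Inf, NA_real_))
  p <- 2 * pt(-abs(stat), df = n - 2)
  p <- ifelse(testable, pmax(p, .Machine$double.xmin), NA_real_)
  out <- data.frame(snp = panel$snps$id, chrom = panel$snps$chrom,
                    pos = panel$snps$pos, beta = beta, se = se, stat = stat,
                    p = p, n = as.integer(n), testable = testable,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Significant SNPs from an association scan
#'
#' @param result an `assoc_result`.
#' @param threshold p-value threshold; SNPs strictly below it are returned.
#' @return character vector of SNP ids.
#' @export
significant_hits <- function(result, threshold = 5e-6) {
  stopifnot_scalar_prob(threshold, "threshold")
  result$snp[!is.na(result$p) & result$testable & result$p < threshold]
}

#' Binary pleiotropy matrix of SNPs significant for multiple traits
#'
#' Restricts the SNP x trait significance incidence to SNPs significant for
#' at least two traits. With an annotation map (SNP id -> gene id) it also
#' reports genes carrying at least two such multi-trait SNPs.
#'
#' @param hit_sets named list (one element per trait) of significant SNP id
#'   vectors.
#' @param annotation optional data.frame with columns `snp`, `gene`.
#' @return A list of class `pleiotropy_matrix`: `incidence` (0/1 matrix,
#'   SNPs x traits), `snp_trait_counts` (named row sums), `genes`
#'   (data.frame `gene`, `n_multi_trait_snps`, or NULL).
#' @export
build_pleiotropy_matrix <- function(hit_sets, annotation = NULL) {
  if (length(hit_sets) < 2L) {
    ba_stop("need hit sets for >= 2 traits", class = "behavarch_config_error")
  }
  all_snps <- sort(unique(unlist(hit_sets)))
  inc <- sapply(hit_sets, function(h) as.integer(all_snps %in% h))
  inc <- matrix(inc, nrow = length(all_snps),
                dimnames = list(all_snps, names(hit_sets)))
  multi <- rowSums(inc) >= 2L
  inc <- inc[multi, , drop = FALSE]
  genes <- NULL
  if (!is.null(annotation)) {
    if (!all(c("snp", "gene") %in% names(annotation))) {
      ba_stop("annotation must have columns `snp` and `gene`",
              class = "behavarch_config_error")
    }
    hit_ann <- annotation[annotation$snp %in% rownames(inc), , drop = FALSE]
    unmatched <- setdiff(annotation$snp, unlist(hit_sets))
    if (length(unmatched) == nrow(annotation)) {
      warning("no annotation SNP ids match any significant SNP")
    }
    if (nrow(hit_ann)) {
      counts <- table(unique(hit_ann[c("snp", "gene")])$gene)
      counts <- counts[counts >= 2L]
      genes <- data.frame(gene = names(counts),
                          n_multi_trait_snps = as.integer(counts),
                          row.names = NULL, stringsAsFactors = FALSE)
      genes <- genes[order(-genes$n_multi_trait_snps, genes$gene), ,
                     drop = FALSE]
      rownames(genes) <- NULL
    }
  }
  structure(list(incidence = inc,
                 snp_trait_counts = rowSums(inc),
                 genes = genes),
            class = "pleiotropy_matrix")
}

#' Assemble the significant-SNP x trait effect-size matrix
#'
#' Rows are the union of all traits' significant SNPs; entry (s, t) is the
#' regression beta of SNP s in trait t's scan regardless of whether s is
#' significant for t (NA only where s was untestable in t).
#'
#' @param scans named list of `assoc_result` objects, one per trait.
#' @param hit_sets named list of significant SNP ids per trait (same
#'   names).
#' @return A numeric matrix of class `effect_matrix` with the per-trait hit
#'   sets stored in `attr(, "hit_sets")`.
#' @export
build_effect_matrix <- function(scans, hit_sets) {
  if (is.null(names(scans)) || !setequal(names(scans), names(hit_sets))) {
    ba_stop("`scans` and `hit_sets` must be named lists over the same traits",
            class = "behavarch_config_error")
  }
  rows <- sort(unique(unlist(hit_sets)))
  if (length(rows) == 0L) ba_stop("no significant SNPs in any trait",
                                  class = "behavarch_empty_input")
  traits <- names(scans)
  em <- matrix(NA_real_, length(rows), length(traits),
               dimnames = list(rows, traits))
  for (tr in traits) {
    sc <- scans[[tr]]
    ix <- match(rows, sc$snp)
    em[, tr] <- sc$beta[ix]  # NA where the SNP is absent or untestable
  }
  attr(em, "hit_sets") <- hit_sets[traits]
  class(em) <- c("effect_matrix", class(em))
  em
}

#' Spearman correlation structure among traits over the effect matrix
#'
#' Pairwise Spearman rank correlation of the trait columns of an effect
#' matrix, on pairwise-complete rows. Pairs with fewer than 3 complete rows
#' are set to NA.
#'
#' @param em an `effect_matrix` (or numeric matrix), SNPs x traits.
#' @return symmetric trait x trait correlation matrix with unit diagonal.
#' @export
trait_correlation_structure <- function(em) {
  if (ncol(em) < 2L) ba_stop("need >= 2 traits", class = "behavarch_config_error")
  m <- unclass(em)
  attr(m, "hit_sets") <- NULL
  rho <- suppressWarnings(cor(m, method = "spearman",
                              use = "pairwise.complete.obs"))
  n_pair <- crossprod(!is.na(m))
  rho[n_pair < 3L] <- NA_real_
  diag(rho) <- 1
  rho[is.nan(rho)] <- NA_real_
  (rho + t(rho)) / 2
}

#' Correlation between genotyping sample size and GWAS p-values
#'
#' Spearman correlation between the per-SNP number of lines tested and the
#' association p-value, pooled over the significant SNPs of all traits. A
#' diagnostic for sample-size-driven inflation of apparent effects (the
#' Beavis effect): a weak correlation indicates p-values are not dominated
#' by which traits happened to be measured on fewer lines.
#'
#' @param scans named list of `assoc_result` objects.
#' @param hit_sets named list of significant SNP ids per trait.
#' @return list with `rho`, `p_value`, `n_snps`, `defined` (FALSE when the
#'   pooled sample sizes are constant, in which case `rho` is NA).
#' @export
samplesize_pvalue_correlation <- function(scans, hit_sets) {
  if (is.null(names(scans)) || !setequal(names(scans), names(hit_sets))) {
    ba_stop("`scans` and `hit_sets` must be named lists over the same traits",
            class = "behavarch_config_error")
  }
  ns <- numeric(0); ps <- numeric(0)
  for (tr in names(scans)) {
    sc <- scans[[tr]]
    ix <- match(hit_sets[[tr]], sc$snp)
    ix <- ix[!is.na(ix)]
    ns <- c(ns, sc$n[ix]); ps <- c(ps, sc$p[ix])
  }
  if (length(ns) < 3L) {
    ba_stop("fewer than 3 pooled significant SNPs",
            class = "behavarch_insufficient_data")
  }
  if (length(unique(ns)) == 1L) {
    return(list(rho = NA_real_, p_value = NA_real_, n_snps = length(ns),
                defined = FALSE))
  }
  ct <- suppressWarnings(cor.test(ns, ps, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n_snps = length(ns),
       defined = TRUE)
}
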