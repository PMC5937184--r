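#' Filter a genotype panel on minor allele frequency
#'
#' Retains SNPs whose minor allele frequency, computed on non-missing calls,
#' is strictly greater than `maf_threshold` (a SNP at exactly the threshold
#' is removed, matching the semantics of the usual `--maf` flag).
#'
#' @param panel a `genotype_panel`.
#' @param maf_threshold exclusive MAF threshold (default 0.01).
#' @return The filtered `genotype_panel` with frequencies recomputed.
#' @export
filter_maf <- function(panel, maf_threshold = 0.01) {
  if (!inherits(panel, "genotype_panel")) ba_stop("`panel` must be a genotype_panel")
  p <- colMeans(panel$X, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- which(!is.na(maf) & maf > maf_threshold)
  if (length(keep) == 0L) {
    ba_stop("no SNPs pass the MAF filter", class = "behavarch_empty_panel")
  }
  new_genotype_panel(panel$line_ids, panel$snps[keep, , drop = FALSE],
                     panel$X[, keep, drop = FALSE], seed = panel$seed)
}

#' Build a genomic relatedness matrix (GRM)
#'
#' Per-SNP standardized estimator over m SNPs:
#' \deqn{A_{jk} = \frac{1}{m}\sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)}}
#' with allele frequencies computed from non-missing calls and missing
#' dosages mean-imputed per SNP before standardization (so imputed entries
#' contribute zero to the numerator).
#'
#' For a fully inbred panel (every non-missing dosage 0 or 2) the per-SNP
#' dosage variance is 4p(1-p), not the Hardy-Weinberg 2p(1-p); with
#' `inbred = "auto"` (default) such panels are detected and standardized by
#' 4p(1-p), the inbred-panel variant of the same estimator, so the mean
#' diagonal is ~1 and Vg stays on the phenotypic scale. Use
#' `inbred = "never"` to force the Hardy-Weinberg denominator.
#'
#' @param panel a `genotype_panel` with >= 2 lines, >= 1 SNP, and no
#'   monomorphic SNPs.
#' @param inbred `"auto"` or `"never"` (see Details).
#' @return A `grm` object: list with `A` (symmetric line x line matrix),
#'   `line_ids`, `n_snps_used`, `inbred`.
#' @export
build_grm <- function(panel, inbred = c("auto", "never")) {
  if (!inherits(panel, "genotype_panel")) ba_stop("`panel` must be a genotype_panel")
  inbred <- match.arg(inbred)
  X <- panel$X
  if (nrow(X) < 2L || ncol(X) < 1L) {
    ba_stop("need >= 2 lines and >= 1 SNP", class = "behavarch_config_error")
  }
  p <- colMeans(X, na.rm = TRUE) / 2
  if (any(is.na(p)) || any(p <= 0) || any(p >= 1)) {
    ba_stop("monomorphic (or all-missing) SNPs present: filter before building the GRM",
            class = "behavarch_monomorphic_error")
  }
  is_inbred <- inbred == "auto" && all(X %in% c(0, 2) | is.na(X))
  denom <- if (is_inbred) 4 * p * (1 - p) else 2 * p * (1 - p)
  # mean imputation: center by 2p, then zero out missing entries
  Z <- sweep(X, 2L, 2 * p, `-`)
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2L, sqrt(denom), `/`)
  A <- tcrossprod(Z) / ncol(X)
  A <- (A + t(A)) / 2
  dimnames(A) <- list(panel$line_ids, panel$line_ids)
  structure(list(A = A, line_ids = panel$line_ids, n_snps_used = ncol(X),
                 inbred = is_inbred),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d lines, built from %d SNPs (mean diagonal %.3f)\n",
              length(x$line_ids), x$n_snps_used, mean(diag(x$A))))
  invisible(x)
}

#' Attach a cached eigendecomposition to a GRM
#'
#' [greml_fit()] needs the eigendecomposition of A; when many phenotypes are
#' analyzed against the same GRM, decomposing once and reusing it avoids the
#' dominant O(n^3) cost per fit.
#'
#' @param grm a `grm` object.
#' @return The same object with an `eig` element (`values`, `vectors`).
#' @export
grm_decompose <- function(grm) {
  if (!inherits(grm, "grm")) ba_stop("`grm` must be a grm object")
  if (is.null(grm$eig)) grm$eig <- eigen(grm$A, symmetric = TRUE)
  grm
}
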