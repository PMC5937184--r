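#' Single-component GREML estimate of SNP heritability
#'
#' Restricted-maximum-likelihood fit of the variance-component model
#' \deqn{y \sim N(\mu 1,\ V_g A + V_e I)}
#' where A is a genomic relatedness matrix. Optimization is
#' average-information (AI) REML warm-started with EM-REML steps; an AI
#' update that leaves the feasible region falls back to an EM step for that
#' iteration. Convergence is declared when the change in the restricted
#' log-likelihood drops below `tol`. Variance components are constrained
#' nonnegative (a component pinned at the boundary sets `boundary`).
#'
#' The heritability is reported as Vg / (Vg + Ve); its standard error comes
#' from the delta method applied to the inverse AI matrix. The
#' likelihood-ratio test against Vg = 0 uses the 50:50 mixture of a point
#' mass at zero and a 1-df chi-square, since the null pins Vg on the
#' parameter boundary.
#'
#' Internally the model is rotated through the eigenbasis of A (cached on
#' the GRM via [grm_decompose()] if present), making each REML iteration
#' O(n).
#'
#' @param grm a `grm` object.
#' @param phenotype numeric vector of per-line values, aligned with
#'   `grm$line_ids`, or named by line id; missing values are dropped.
#' @param tol convergence tolerance on the restricted log-likelihood.
#' @param max_iter maximum REML iterations.
#' @param n_em number of EM warm-start iterations.
#' @return A list of class `greml_result`: `vg`, `ve`, `vp` (= vg + ve),
#'   `h2`, `se_h2`, `loglik`, `loglik_null`, `lrt`, `p_value`, `n_lines`,
#'   `n_snps`, `converged`, `boundary`, `n_iter`.
#' @export
greml_fit <- function(grm, phenotype, tol = 1e-8, max_iter = 100L,
                      n_em = 3L) {
  if (!inherits(grm, "grm")) ba_stop("`grm` must be a grm object")
  y <- align_phenotype(grm$line_ids, phenotype)
  ok <- !is.na(y)
  if (sum(ok) < 10L) {
    ba_stop("need >= 10 lines with phenotype and GRM entries",
            class = "behavarch_insufficient_data")
  }
  if (var(y[ok]) <= 0) {
    ba_stop("phenotype has zero variance", class = "behavarch_degenerate_input")
  }
  if (all(ok) && !is.null(grm$eig)) {
    eig <- grm$eig
  } else {
    eig <- eigen(grm$A[ok, ok, drop = FALSE], symmetric = TRUE)
  }
  res <- greml_reml(eig$values, crossprod(eig$vectors, y[ok]),
                    crossprod(eig$vectors, rep(1, sum(ok))),
                    tol = tol, max_iter = max_iter, n_em = n_em)
  res$n_lines <- sum(ok)
  res$n_snps <- grm$n_snps_used
  class(res) <- "greml_result"
  res
}

align_phenotype <- function(line_ids, phenotype) {
  if (!is.null(names(phenotype))) {
    y <- phenotype[line_ids]
  } else {
    if (length(phenotype) != length(line_ids)) {
      ba_stop("phenotype length does not match the GRM and is unnamed",
              class = "behavarch_config_error")
    }
    y <- phenotype
  }
  as.numeric(y)
}

# Core REML in the rotated basis: D = eigenvalues of A, yt = U'y, xt = U'1.
greml_reml <- function(D, yt, xt, tol, max_iter, n_em) {
  n <- length(yt)
  yt <- as.numeric(yt); xt <- as.numeric(xt)
  vp0 <- (sum(yt^2) - sum(xt * yt)^2 / sum(xt^2)) / (n - 1)
  floor_v <- 1e-8 * vp0

  # restricted log-likelihood and the quantities reused by EM/AI updates
  eval_at <- function(vg, ve) {
    d <- vg * D + ve
    if (any(d <= 0)) return(NULL)
    w <- 1 / d
    v <- w * xt
    cxx <- sum(xt * v)
    Py <- w * yt - v * (sum(v * yt) / cxx)
    ypy <- sum(yt * Py)
    ll <- -0.5 * ((n - 1) * log(2 * pi) + sum(log(d)) + log(cxx) + ypy)
    Pa <- function(a) w * a - v * (sum(v * a) / cxx)   # P applied to a vector
    list(vg = vg, ve = ve, w = w, v = v, cxx = cxx, Py = Py, ll = ll,
         tr_PA = sum(w * D) - sum(v^2 * D) / cxx,
         tr_P = sum(w) - sum(v^2) / cxx,
         yPAPy = sum(D * Py^2), yPPy = sum(Py^2), Pa = Pa)
  }

  vg <- ve <- vp0 / 2
  st <- eval_at(vg, ve)
  converged <- FALSE
  it <- 0L
  ll_trace <- st$ll
  em_step <- function(st) {
    vg2 <- st$vg + st$vg^2 * (st$yPAPy - st$tr_PA) / n
    ve2 <- st$ve + st$ve^2 * (st$yPPy - st$tr_P) / n
    c(max(vg2, floor_v), max(ve2, floor_v))
  }
  ai_matrix <- function(st) {
    t1 <- D * st$Py
    ai <- matrix(0, 2, 2)
    ai[1, 1] <- 0.5 * sum(t1 * st$Pa(t1))
    ai[1, 2] <- ai[2, 1] <- 0.5 * sum(t1 * st$Pa(st$Py))
    ai[2, 2] <- 0.5 * sum(st$Py * st$Pa(st$Py))
    ai
  }

  while (it < max_iter) {
    it <- it + 1L
    if (it <= n_em) {
      theta <- em_step(st)
    } else {
      score <- c(-0.5 * (st$tr_PA - st$yPAPy), -0.5 * (st$tr_P - st$yPPy))
      ai <- ai_matrix(st)
      step <- tryCatch(solve(ai, score), error = function(e) NULL)
      if (is.null(step)) {
        theta <- em_step(st)
      } else {
        # clamp components the AI step drives negative to the boundary
        theta <- pmax(c(st$vg, st$ve) + step, floor_v)
        if (is.null(eval_at(theta[1], theta[2]))) theta <- em_step(st)
      }
    }
    st_new <- eval_at(theta[1], theta[2])
    if (is.null(st_new)) break
    ll_trace <- c(ll_trace, st_new$ll)
    if (it > n_em && abs(st_new$ll - st$ll) < tol) {
      st <- st_new
      converged <- TRUE
      break
    }
    st <- st_new
  }
  vg <- st$vg; ve <- st$ve
  boundary <- vg <= floor_v * 1.001 || ve <= floor_v * 1.001
  vp <- vg + ve
  h2 <- vg / vp

  # delta-method SE of h2 from the inverse AI matrix
  se_h2 <- tryCatch({
    covm <- solve(ai_matrix(st))
    grad <- c(ve, -vg) / vp^2
    sqrt(max(0, as.numeric(t(grad) %*% covm %*% grad)))
  }, error = function(e) NA_real_)

  # null model: vg = 0, ve at its REML optimum (closed form)
  ve0 <- (sum(yt^2) - sum(xt * yt)^2 / sum(xt^2)) / (n - 1)
  ll0 <- eval_at(0, ve0)$ll
  lrt <- max(0, 2 * (st$ll - ll0))
  p <- 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)

  list(vg = vg, ve = ve, vp = vp, h2 = h2, se_h2 = se_h2,
       loglik = st$ll, loglik_null = ll0, lrt = lrt, p_value = p,
       converged = converged, boundary = boundary, n_iter = it,
       ll_trace = ll_trace)
}

#' @export
print.greml_result <- function(x, ...) {
  cat(sprintf("GREML: h2 = %.4f (SE %.4f), Vg = %.4g, Ve = %.4g, p = %.3g [%s]\n",
              x$h2, x$se_h2, x$vg, x$ve, x$p_value,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' GREML restricted to a named SNP subset
#'
#' Rebuilds the GRM from the named SNPs only (e.g. the genome-wide
#' significant SNPs of a trait) and reruns [greml_fit()]. With the full SNP
#' set this reduces exactly to the genome-wide fit.
#'
#' @param panel a `genotype_panel`.
#' @param snp_ids SNP identifiers to retain.
#' @param phenotype per-line phenotype (see [greml_fit()]).
#' @param maf_threshold optional MAF filter applied to the subset before
#'   building the GRM (default 0: no additional filtering).
#' @param ... passed to [greml_fit()].
#' @return A `greml_result` with an extra `n_subset_snps` element.
#' @export
greml_on_snp_subset <- function(panel, snp_ids, phenotype, maf_threshold = 0,
                                ...) {
  if (!inherits(panel, "genotype_panel")) ba_stop("`panel` must be a genotype_panel")
  ix <- match(snp_ids, panel$snps$id)
  if (anyNA(ix)) {
    ba_stop(paste("unknown SNP ids:",
                  paste(head(snp_ids[is.na(ix)], 5L), collapse = ", ")),
            class = "behavarch_lookup_error")
  }
  if (length(ix) == 0L) ba_stop("empty SNP subset", class = "behavarch_empty_panel")
  sub <- new_genotype_panel(panel$line_ids, panel$snps[ix, , drop = FALSE],
                            panel$X[, ix, drop = FALSE], seed = panel$seed)
  if (maf_threshold > 0) sub <- filter_maf(sub, maf_threshold)
  res <- greml_fit(build_grm(sub), phenotype, ...)
  res$n_subset_snps <- nrow(sub$snps)
  res
}

#' Screen a battery of traits for significant SNP heritability
#'
#' @param results named list of `greml_result` objects (one per trait).
#' @param alpha significance level; traits with LRT p strictly below it are
#'   retained.
#' @return character vector of retained trait names.
#' @export
screen_heritable_traits <- function(results, alpha = 0.05) {
  if (length(results) < 1L) ba_stop("no GREML results supplied",
                                    class = "behavarch_empty_input")
  p <- vapply(results, function(r) r$p_value, numeric(1))
  names(results)[p < alpha]
}
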