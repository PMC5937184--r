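#' Bayesian linear mixed model of effect size via Gibbs sampling
#'
#' Fits the Gaussian linear mixed model
#' \deqn{y = X b + \sum_k Z_k u_k + e,\quad u_k \sim N(0, \sigma_k^2 I),\ e \sim N(0, \sigma_e^2 I)}
#' by Gibbs sampling with a flat prior on the fixed effects and independent
#' inverse-gamma priors (default shape = scale = 0.001) on every variance
#' component. Fixed effects are behavioral-category levels (treatment
#' coding); random terms are chosen from:
#' \describe{
#'   \item{"study"}{random intercept per study (always included).}
#'   \item{"sample_size"}{random slope of centered/scaled sample size per study.}
#'   \item{"generations"}{random slope of centered/scaled log10 generations per study.}
#'   \item{"cross_type"}{random intercept per cross type.}
#' }
#' Every column block of each Z_k is orthogonal across group levels, so all
#' full conditionals are scalar or small-dimensional and the sampler is
#' exact conjugate Gibbs.
#'
#' Reported are posterior means, 95% highest-posterior-density intervals,
#' the deviance information criterion (DIC = Dbar + pD with
#' pD = Dbar - D(posterior means)), and the Gelman-Rubin potential
#' scale-reduction factor (PSRF) per parameter computed across `n_chains`
#' independent chains. A PSRF above 1.1 on any parameter sets
#' `convergence_warning`.
#'
#' @param records a `qtl_table`.
#' @param random_terms character vector from
#'   `c("sample_size", "generations", "cross_type")`; a per-study random
#'   intercept is always added.
#' @param burn_in,n_iter,thin,n_chains MCMC settings. `n_iter` is the total
#'   chain length including burn-in.
#' @param prior_shape,prior_scale inverse-gamma hyperparameters shared by
#'   all variance components.
#' @param seed integer seed; chains are deterministic given it.
#' @param reference baseline category for the treatment coding.
#' @return A list of class `bayes_lmm_fit` with elements `posterior`
#'   (data.frame: `term`, `mean`, `hpd_lower`, `hpd_upper`, `psrf`),
#'   `dic`, `deviance_bar`, `p_d`, `samples` (pooled matrix),
#'   `convergence_warning`, `settings`.
#' @export
fit_bayes_lmm <- function(records,
                          random_terms = c("sample_size", "generations"),
                          burn_in = 10000L, n_iter = 300000L, thin = 10L,
                          n_chains = 5L, prior_shape = 0.001,
                          prior_scale = 0.001, seed = 1L, reference = NULL) {
  check_qtl_records(records)
  bad <- setdiff(random_terms, c("sample_size", "generations", "cross_type"))
  if (length(bad)) {
    ba_stop(paste("unknown random terms:", paste(bad, collapse = ", ")),
            class = "behavarch_config_error")
  }
  if (burn_in >= n_iter) ba_stop("burn_in must be < n_iter",
                                 class = "behavarch_config_error")
  df <- prepare_lmm_frame(records, reference)
  X <- if (nlevels(df$behavioral_category) > 1L) {
    stats::model.matrix(~behavioral_category, df)
  } else {
    matrix(1, nrow(df), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  y <- df$effect_size_pve

  terms <- build_random_terms(df, random_terms)
  fit <- with_seed(seed, {
    chains <- lapply(seq_len(n_chains), function(ch) {
      gibbs_lmm_chain(y, X, terms, n_iter = n_iter, burn_in = burn_in,
                      thin = thin, a = prior_shape, b = prior_scale)
    })
    summarize_gibbs_chains(chains, y, X, terms)
  })
  fit$settings <- list(random_terms = random_terms, burn_in = burn_in,
                       n_iter = n_iter, thin = thin, n_chains = n_chains,
                       prior_shape = prior_shape, prior_scale = prior_scale,
                       seed = seed)
  class(fit) <- "bayes_lmm_fit"
  fit
}

# Random-effect design terms. Each term is a grouping index + covariate
# value per observation; Z_k columns are orthogonal across levels.
build_random_terms <- function(df, random_terms) {
  terms <- list(study = list(group = as.integer(df$study_id),
                             n_levels = nlevels(df$study_id),
                             value = rep(1, nrow(df))))
  if ("sample_size" %in% random_terms) {
    terms$sample_size <- list(group = as.integer(df$study_id),
                              n_levels = nlevels(df$study_id),
                              value = df$sample_size_z)
  }
  if ("generations" %in% random_terms) {
    terms$generations <- list(group = as.integer(df$study_id),
                              n_levels = nlevels(df$study_id),
                              value = df$generations_z)
  }
  if ("cross_type" %in% random_terms) {
    ct <- factor(df$cross_type)
    terms$cross_type <- list(group = as.integer(ct), n_levels = nlevels(ct),
                             value = rep(1, nrow(df)))
  }
  terms
}

gibbs_lmm_chain <- function(y, X, terms, n_iter, burn_in, thin, a, b) {
  n <- length(y); p <- ncol(X); K <- length(terms)
  XtX <- crossprod(X)
  R_X <- chol(XtX)                      # for fixed-effect draws
  ztz <- lapply(terms, function(tm) {
    as.numeric(rowsum(tm$value^2, tm$group, reorder = TRUE))
  })
  # state
  vy <- var(y)
  sig_e <- vy / 2
  sig_k <- rep(vy / (2 * K), K)
  u <- lapply(terms, function(tm) rep(0, tm$n_levels))
  bvec <- rep(0, p)

  keep <- seq(burn_in + thin, n_iter, by = thin)
  n_keep <- length(keep)
  par_names <- c(colnames(X), paste0("var_", names(terms)), "var_residual")
  samples <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
  deviance <- numeric(n_keep)
  u_mean <- lapply(terms, function(tm) rep(0, tm$n_levels))
  s <- 0L

  zu_total <- rep(0, n)
  zu_k <- lapply(terms, function(tm) rep(0, n))

  for (it in seq_len(n_iter)) {
    # fixed effects | rest (flat prior)
    r <- y - zu_total
    mu_b <- backsolve(R_X, backsolve(R_X, crossprod(X, r), transpose = TRUE))
    bvec <- as.numeric(mu_b + sqrt(sig_e) * backsolve(R_X, rnorm(p)))
    xb <- as.numeric(X %*% bvec)

    # random effects | rest, one orthogonal block at a time
    for (k in seq_len(K)) {
      tm <- terms[[k]]
      r_k <- y - xb - (zu_total - zu_k[[k]])
      ztr <- as.numeric(rowsum(tm$value * r_k, tm$group, reorder = TRUE))
      prec <- ztz[[k]] / sig_e + 1 / sig_k[k]
      mean_u <- (ztr / sig_e) / prec
      u[[k]] <- mean_u + rnorm(tm$n_levels) / sqrt(prec)
      new_zu <- tm$value * u[[k]][tm$group]
      zu_total <- zu_total - zu_k[[k]] + new_zu
      zu_k[[k]] <- new_zu
    }

    # variance components | rest
    for (k in seq_len(K)) {
      sig_k[k] <- 1 / rgamma(1, shape = a + terms[[k]]$n_levels / 2,
                             rate = b + sum(u[[k]]^2) / 2)
    }
    e <- y - xb - zu_total
    sig_e <- 1 / rgamma(1, shape = a + n / 2, rate = b + sum(e * e) / 2)

    if (s < n_keep && it == keep[s + 1L]) {
      s <- s + 1L
      samples[s, ] <- c(bvec, sig_k, sig_e)
      fitted <- xb + zu_total
      deviance[s] <- -2 * sum(dnorm(y, fitted, sqrt(sig_e), log = TRUE))
      for (k in seq_len(K)) u_mean[[k]] <- u_mean[[k]] + u[[k]]
    }
  }
  u_mean <- lapply(u_mean, function(v) v / n_keep)
  list(samples = samples, deviance = deviance, u_mean = u_mean)
}

summarize_gibbs_chains <- function(chains, y, X, terms) {
  samples <- do.call(rbind, lapply(chains, `[[`, "samples"))
  par_names <- colnames(samples)
  post_mean <- colMeans(samples)
  hpd <- t(apply(samples, 2L, hpd_interval))
  psrf <- vapply(par_names, function(nm) {
    gelman_rubin(lapply(chains, function(ch) ch$samples[, nm]))
  }, numeric(1))

  # DIC: Dbar from the samples; D(theta_bar) at posterior means of all
  # location parameters (b, u) and of the residual variance.
  dbar <- mean(unlist(lapply(chains, `[[`, "deviance")))
  K <- length(terms)
  p <- ncol(X)
  b_bar <- post_mean[seq_len(p)]
  u_bar <- vector("list", K)
  for (k in seq_len(K)) {
    u_bar[[k]] <- Reduce(`+`, lapply(chains, function(ch) ch$u_mean[[k]])) /
      length(chains)
  }
  fitted_bar <- as.numeric(X %*% b_bar)
  for (k in seq_len(K)) {
    tm <- terms[[k]]
    fitted_bar <- fitted_bar + tm$value * u_bar[[k]][tm$group]
  }
  sig_e_bar <- post_mean[["var_residual"]]
  d_hat <- -2 * sum(dnorm(y, fitted_bar, sqrt(sig_e_bar), log = TRUE))
  p_d <- dbar - d_hat
  dic <- dbar + p_d

  posterior <- data.frame(term = par_names, mean = post_mean,
                          hpd_lower = hpd[, 1], hpd_upper = hpd[, 2],
                          psrf = psrf, row.names = NULL,
                          stringsAsFactors = FALSE)
  warn <- any(psrf > 1.1, na.rm = TRUE)
  if (warn) {
    warning("PSRF > 1.1 on at least one parameter: chains may not have converged")
  }
  list(posterior = posterior, dic = dic, deviance_bar = dbar, p_d = p_d,
       samples = samples, convergence_warning = warn)
}

# Shortest interval containing `prob` of the sampled mass.
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  gap <- max(1L, min(n - 1L, floor(n * prob)))
  first <- seq_len(n - gap)
  width <- x[first + gap] - x[first]
  i <- which.min(width)
  c(x[i], x[i + gap])
}

# Gelman-Rubin potential scale reduction over a list of chains.
gelman_rubin <- function(chain_list) {
  m <- length(chain_list)
  if (m < 2L) return(NA_real_)
  n <- length(chain_list[[1]])
  means <- vapply(chain_list, mean, numeric(1))
  vars <- vapply(chain_list, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank candidate random-effect structures by DIC
#'
#' Fits [fit_bayes_lmm()] for each candidate structure and orders them by
#' ascending DIC (lower is better). The default candidates are the seven
#' non-empty subsets of \{sample_size, generations, cross_type\}, each on
#' top of the per-study random intercept.
#'
#' @param records a `qtl_table`.
#' @param candidates list of character vectors of random terms.
#' @param ... passed to [fit_bayes_lmm()] (chain settings, seed, ...).
#' @return data.frame of class `dic_ranking`, ordered by DIC, with columns
#'   `structure`, `dic`, `p_d`, `convergence_warning`, `error`; fitted
#'   models in `attr(, "fits")`.
#' @export
rank_models_by_dic <- function(records, candidates = default_dic_candidates(),
                               ...) {
  if (length(candidates) < 1L) {
    ba_stop("need at least one candidate structure",
            class = "behavarch_config_error")
  }
  fits <- vector("list", length(candidates))
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    label <- paste(candidates[[i]], collapse = "+")
    res <- tryCatch(
      fit_bayes_lmm(records, random_terms = candidates[[i]], ...),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(structure = label, dic = NA_real_,
                              p_d = NA_real_, convergence_warning = NA,
                              error = conditionMessage(res),
                              stringsAsFactors = FALSE)
    } else {
      fits[[i]] <- res
      rows[[i]] <- data.frame(structure = label, dic = res$dic,
                              p_d = res$p_d,
                              convergence_warning = res$convergence_warning,
                              error = NA_character_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  ord <- order(out$dic, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits[ord]
  class(out) <- c("dic_ranking", "data.frame")
  out
}

#' @rdname rank_models_by_dic
#' @export
default_dic_candidates <- function() {
  base <- c("sample_size", "generations", "cross_type")
  out <- list()
  for (k in 1:3) {
    cmb <- combn(base, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}
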