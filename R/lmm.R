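#' Frequentist linear mixed model of effect size on behavioral category
#'
#' REML fit (via \pkg{lme4}/\pkg{lmerTest}) of per-locus PVE on behavioral
#' category as a fixed effect, with a configurable random-effect structure.
#' The default structure is a random intercept plus independent random
#' slopes for centered-and-scaled sample size and generations diverged,
#' grouped by study: the study is the natural exchangeable unit, and the
#' two covariates enter as within-study slopes.
#'
#' Covariates `sample_size_z` and `generations_z` (centered, scaled) are
#' added to the model frame before fitting and can be referenced in
#' `random`.
#'
#' @param records a `qtl_table`.
#' @param random right-hand-side random-effects term as a string, e.g.
#'   `"(1 + sample_size_z + generations_z || study_id)"`. `NULL` fits an
#'   ordinary linear model (all random-effect variances fixed at zero).
#' @param reference category used as the fixed-effect baseline (default:
#'   first level alphabetically).
#' @return A list of class `lmm_fit`: `fixed_effects` (data.frame with
#'   `term`, `estimate`, `se`, `df`, `p_value`), `random_variances` (named
#'   vector, residual last), `converged`, `singular`, `loglik`, `formula`,
#'   and the underlying `model` object.
#' @export
fit_lmm_effects <- function(records,
                            random = "(1 + sample_size_z + generations_z || study_id)",
                            reference = NULL) {
  check_qtl_records(records)
  if (length(unique(records$behavioral_category)) < 2L) {
    ba_stop("need >= 2 behavioral categories", class = "behavarch_insufficient_data")
  }
  df <- prepare_lmm_frame(records, reference)
  if (is.null(random)) {
    fml <- effect_size_pve ~ behavioral_category
    fit <- lm(fml, data = df)
    sm <- summary(fit)$coefficients
    fe <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                     df = fit$df.residual, p_value = sm[, 4],
                     row.names = NULL, stringsAsFactors = FALSE)
    out <- list(fixed_effects = fe,
                random_variances = c(residual = summary(fit)$sigma^2),
                converged = TRUE, singular = FALSE,
                loglik = as.numeric(logLik(fit)),
                formula = deparse(fml), model = fit)
  } else {
    fml <- as.formula(paste("effect_size_pve ~ behavioral_category +", random))
    fit <- lmerTest::lmer(fml, data = df, REML = TRUE)
    sm <- coef(summary(fit))
    vc <- as.data.frame(lme4::VarCorr(fit))
    rv <- setNames(vc$vcov, ifelse(is.na(vc$var1), vc$grp,
                                   paste(vc$grp, vc$var1, sep = ":")))
    names(rv)[vc$grp == "Residual"] <- "residual"
    msgs <- fit@optinfo$conv$lme4$messages
    # boundary/singular messages are flagged via `singular`, not `converged`
    msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
    fe <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                     se = sm[, "Std. Error"], df = sm[, "df"],
                     p_value = sm[, "Pr(>|t|)"],
                     row.names = NULL, stringsAsFactors = FALSE)
    out <- list(fixed_effects = fe, random_variances = rv,
                converged = is.null(msgs) || length(msgs) == 0L,
                singular = lme4::isSingular(fit),
                loglik = as.numeric(logLik(fit)),
                formula = deparse(fml), model = fit)
  }
  class(out) <- "lmm_fit"
  out
}

prepare_lmm_frame <- function(records, reference = NULL) {
  df <- as.data.frame(records)
  df$behavioral_category <- factor(df$behavioral_category)
  if (!is.null(reference)) {
    if (!reference %in% levels(df$behavioral_category)) {
      ba_stop(sprintf("reference category '%s' not present", reference),
              class = "behavarch_lookup_error")
    }
    df$behavioral_category <- stats::relevel(df$behavioral_category, reference)
  }
  df$study_id <- factor(df$study_id)
  df$sample_size_z <- as.numeric(scale(df$sample_size))
  df$generations_z <- as.numeric(scale(log10(pmax(df$generations_diverged, 1))))
  df
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("linear mixed model fit (", x$formula, ")\n", sep = "")
  cat(if (x$converged) "converged" else "DID NOT CONVERGE",
      if (x$singular) "(singular fit)" else "", "\n")
  print(x$fixed_effects, digits = 4)
  invisible(x)
}
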