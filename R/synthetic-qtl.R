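#' Configuration for the synthetic QTL meta-table generator
#'
#' Describes the study conditions the generator emulates: a compiled table of
#' significant behavioral QTL, each reporting its effect size as percent
#' phenotypic variance explained (PVE), a significance score (LOD or
#' -log10 P), the behavioral category, the cross and its evolutionary
#' divergence, and the mapping sample size.
#'
#' The defaults emulate a compiled literature table of 1007 loci spread over
#' ten behavioral categories and 114 studies, in which courtship loci
#' (n = 124) have roughly three-fold larger mean PVE than the remaining
#' categories, feeding (n = 11) is also elevated, and emotion/social loci sit
#' below the overall mean. Per-category PVE is exponential with the
#' configured mean (truncated to (0, 100] by resampling), the architecture
#' expected for behavioral traits: many loci of small effect and a tail of
#' moderate-to-large ones. Mean PVE additionally shifts with the study's
#' evolutionary divergence via `divergence_effect_slope` (PVE units per
#' decade of years diverged, centered so category means are preserved).
#'
#' @param categories character vector of behavioral category labels.
#' @param n_loci_per_category integer vector (recycled) of loci per category.
#' @param mean_pve numeric vector (recycled) of per-category mean PVE on
#'   (0, 100).
#' @param n_studies number of simulated source studies.
#' @param sample_size_range integer bounds for per-study mapping sample size.
#' @param fraction_interspecific proportion of studies that are crosses
#'   between species, in [0, 1].
#' @param years_range_intra,years_range_inter lognormal location bounds
#'   (years since divergence) for intra- and interspecific crosses.
#' @param generations_per_year_range bounds for generations per year.
#' @param divergence_effect_slope shift in mean PVE per unit of
#'   log10(years diverged), centered at the configured mixture mean.
#' @param seed integer seed; all randomness in [gen_qtl_table()] flows
#'   through it.
#'
#' @return An object of class `qtl_sim_config`.
#' @seealso [gen_qtl_table()]
#' @export
qtl_sim_config <- function(categories = c("courtship", "feeding", "emotion",
                                          "social", "locomotion", "learning",
                                          "aggression", "preference",
                                          "wariness", "migration"),
                           n_loci_per_category = c(124L, 11L, 109L, 109L,
                                                   109L, 109L, 109L, 109L,
                                                   109L, 109L),
                           mean_pve = c(22, 18, 5.5, 6.5,
                                        8.2, 8.2, 8.2, 8.2, 8.2, 8.2),
                           n_studies = 114L,
                           sample_size_range = c(50L, 1000L),
                           fraction_interspecific = 0.3,
                           years_range_intra = c(1e4, 1e6),
                           years_range_inter = c(1e6, 5e8),
                           generations_per_year_range = c(0.5, 10),
                           divergence_effect_slope = 2.5,
                           seed = 1L) {
  n_cat <- length(categories)
  if (n_cat < 1L) ba_stop("at least one category required",
                          class = "behavarch_config_error")
  n_loci_per_category <- rep_len(as.integer(n_loci_per_category), n_cat)
  mean_pve <- rep_len(as.numeric(mean_pve), n_cat)
  if (any(n_loci_per_category < 0L)) {
    ba_stop("locus counts must be >= 0", class = "behavarch_config_error")
  }
  if (any(!is.finite(mean_pve)) || any(mean_pve <= 0) || any(mean_pve >= 100)) {
    ba_stop("per-category mean PVE must lie in (0, 100)",
            class = "behavarch_config_error")
  }
  stopifnot_scalar_prob(fraction_interspecific, "fraction_interspecific")
  if (sample_size_range[1] < 2L || sample_size_range[2] < sample_size_range[1]) {
    ba_stop("invalid sample_size_range", class = "behavarch_config_error")
  }
  structure(
    list(categories = categories,
         n_loci_per_category = n_loci_per_category,
         mean_pve = mean_pve,
         n_studies = as.integer(n_studies),
         sample_size_range = as.integer(sample_size_range),
         fraction_interspecific = fraction_interspecific,
         years_range_intra = years_range_intra,
         years_range_inter = years_range_inter,
         generations_per_year_range = generations_per_year_range,
         divergence_effect_slope = divergence_effect_slope,
         seed = as.integer(seed)),
    class = "qtl_sim_config"
  )
}

#' Generate a synthetic compiled QTL table
#'
#' Simulates studies (species pair, cross type, divergence, sample size) and
#' then loci within categories assigned to studies. Per-locus PVE is drawn
#' from an exponential distribution whose mean is the category mean shifted
#' by the study's divergence (see [qtl_sim_config()]), truncated to
#' (0, 100]. Each locus carries either a LOD score or a -log10 P value (or
#' both), a genome location, and all cross metadata the meta-analysis
#' consumes.
#'
#' @param config a [qtl_sim_config()] object.
#' @return A `data.frame` of class `qtl_table`, one row per locus, with
#'   columns `study_id`, `species_a`, `species_b`, `taxon_class`,
#'   `behavioral_category`, `trait_name`, `effect_size_pve`, `lod`,
#'   `neglog10_p`, `sample_size`, `generations_diverged`, `years_diverged`,
#'   `cross_type`, `chrom`, `pos`. The generating seed is stored in
#'   `attr(, "seed")`.
#' @export
gen_qtl_table <- function(config) {
  if (!inherits(config, "qtl_sim_config")) {
    ba_stop("`config` must be a qtl_sim_config", class = "behavarch_config_error")
  }
  with_seed(config$seed, {
    n_total <- sum(config$n_loci_per_category)
    studies <- sim_studies(config)
    if (n_total == 0L) {
      tab <- empty_qtl_table()
      attr(tab, "seed") <- config$seed
      return(tab)
    }

    category <- rep(config$categories, config$n_loci_per_category)
    mean_cat <- rep(config$mean_pve, config$n_loci_per_category)
    study_ix <- sample.int(config$n_studies, n_total, replace = TRUE)

    # Center the divergence effect at the mixture mean of log10(years) so
    # configured category means are preserved in expectation.
    center <- mean(log10(studies$years_diverged))
    mu <- mean_cat + config$divergence_effect_slope *
      (log10(studies$years_diverged[study_ix]) - center)
    mu <- pmax(mu, 0.5)
    pve <- rexp_truncated(n_total, mu, upper = 100)

    # Significance reporting varies by study: roughly half report LOD,
    # the rest -log10 P (derived from an underlying LOD draw).
    lod_raw <- runif(n_total, 2, 15)
    reports_lod <- studies$reports_lod[study_ix]
    lod <- ifelse(reports_lod, lod_raw, NA_real_)
    nlp <- ifelse(reports_lod, NA_real_, lod_to_neglog10p(lod_raw))

    tab <- data.frame(
      study_id = studies$study_id[study_ix],
      species_a = studies$species_a[study_ix],
      species_b = studies$species_b[study_ix],
      taxon_class = studies$taxon_class[study_ix],
      behavioral_category = category,
      trait_name = paste0(category, "_trait_",
                          unlist(lapply(config$n_loci_per_category, seq_len))),
      effect_size_pve = pve,
      lod = lod,
      neglog10_p = nlp,
      sample_size = studies$sample_size[study_ix],
      generations_diverged = studies$generations_diverged[study_ix],
      years_diverged = studies$years_diverged[study_ix],
      cross_type = studies$cross_type[study_ix],
      chrom = paste0("chr", sample.int(10L, n_total, replace = TRUE)),
      pos = sample.int(1e8L, n_total, replace = TRUE),
      stringsAsFactors = FALSE
    )
    class(tab) <- c("qtl_table", "data.frame")
    attr(tab, "seed") <- config$seed
    tab
  })
}

# Study-level metadata: cross type, divergence, sample size, taxon.
sim_studies <- function(config) {
  ns <- config$n_studies
  inter <- runif(ns) < config$fraction_interspecific
  lyr <- ifelse(inter,
                runif(ns, log10(config$years_range_inter[1]),
                      log10(config$years_range_inter[2])),
                runif(ns, log10(config$years_range_intra[1]),
                      log10(config$years_range_intra[2])))
  years <- 10^lyr
  gpy <- runif(ns, config$generations_per_year_range[1],
               config$generations_per_year_range[2])
  taxa <- c("mammal", "bird", "fish", "insect", "crustacean")
  genus <- paste0("genus", sample.int(40L, ns, replace = TRUE))
  sp_a <- paste0(genus, "_sp1")
  sp_b <- ifelse(inter, paste0(genus, "_sp2"), sp_a)
  list(
    study_id = sprintf("study_%03d", seq_len(ns)),
    species_a = sp_a,
    species_b = sp_b,
    taxon_class = sample(taxa, ns, replace = TRUE),
    cross_type = ifelse(inter, "interspecific", "intraspecific"),
    years_diverged = years,
    generations_diverged = years * gpy,
    sample_size = sample(seq(config$sample_size_range[1],
                             config$sample_size_range[2]), ns, replace = TRUE),
    reports_lod = runif(ns) < 0.5
  )
}

# Exponential draws with per-element mean, resampled into (0, upper].
rexp_truncated <- function(n, mean, upper) {
  x <- rexp(n, rate = 1 / mean)
  bad <- which(x <= 0 | x > upper)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- rexp(length(bad), rate = 1 / mean[bad])
    bad <- bad[x[bad] <= 0 | x[bad] > upper]
    guard <- guard + 1L
    if (guard > 1000L) ba_stop("truncated exponential sampler failed to mix")
  }
  x
}

empty_qtl_table <- function() {
  tab <- data.frame(
    study_id = character(), species_a = character(), species_b = character(),
    taxon_class = character(), behavioral_category = character(),
    trait_name = character(), effect_size_pve = numeric(), lod = numeric(),
    neglog10_p = numeric(), sample_size = integer(),
    generations_diverged = numeric(), years_diverged = numeric(),
    cross_type = character(), chrom = character(), pos = integer(),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("qtl_table", "data.frame")
  tab
}
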