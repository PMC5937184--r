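#' Pipeline configuration
#'
#' A flat configuration object for [run_pipeline()]: which stages to run,
#' thresholds, seed, and the output directory. Every artifact the pipeline
#' writes embeds the seed and threshold set.
#'
#' @param stages subset of
#'   `c("simulate", "meta", "grm", "greml", "gwas", "pleiotropy", "direction")`.
#' @param out_dir output directory (created if needed).
#' @param seed master seed for the run.
#' @param qtl_config a [qtl_sim_config()] (used by the simulate/meta stages;
#'   defaults to the package defaults reseeded from `seed`).
#' @param panel_config a [panel_sim_config()] for the genotype stages;
#'   `NULL` gives a small default panel with fork and chain trait pairs.
#' @param gwas_p GWAS significance threshold (default 5e-6).
#' @param greml_alpha GREML screening level (default 0.05).
#' @param maf MAF filter for the GRM (default 0.01).
#' @param screen_high,screen_low directionality screening bounds.
#' @param n_perm_meta,n_perm_direction permutation counts.
#' @return list of class `run_config`.
#' @export
run_config <- function(stages = c("simulate", "meta", "grm", "greml", "gwas",
                                  "pleiotropy", "direction"),
                       out_dir = tempfile("behavarch_run_"), seed = 1L,
                       qtl_config = NULL, panel_config = NULL,
                       gwas_p = 5e-6, greml_alpha = 0.05, maf = 0.01,
                       screen_high = 0.5, screen_low = 0.1,
                       n_perm_meta = 10000L, n_perm_direction = 1000L) {
  known <- c("simulate", "meta", "grm", "greml", "gwas", "pleiotropy",
             "direction")
  bad <- setdiff(stages, known)
  if (length(bad)) ba_stop(paste("unknown stage(s):", paste(bad, collapse = ", ")),
                           class = "behavarch_config_error")
  for (nm in c("gwas_p", "greml_alpha")) {
    stopifnot_scalar_prob(get(nm), nm)
  }
  structure(list(stages = stages, out_dir = out_dir, seed = as.integer(seed),
                 qtl_config = qtl_config, panel_config = panel_config,
                 gwas_p = gwas_p, greml_alpha = greml_alpha, maf = maf,
                 screen_high = screen_high, screen_low = screen_low,
                 n_perm_meta = as.integer(n_perm_meta),
                 n_perm_direction = as.integer(n_perm_direction)),
            class = "run_config")
}

default_pipeline_panel <- function(seed) {
  n_snps <- 1200L
  panel_sim_config(
    n_lines = 300L, n_snps = n_snps, inbred = TRUE, seed = seed,
    traits = list(
      trait_spec("trait_h2_null", causal_snps = integer(), h2 = 0),
      trait_spec("trait_h2_half", causal_snps = 1:50, beta = 1, h2 = 0.5),
      trait_spec("fork_a", causal_snps = 101:115, beta = 2.5, h2 = 0.8),
      trait_spec("fork_b", causal_snps = 101:115, beta = 2.5, h2 = 0.8),
      trait_spec("chain_parent", causal_snps = 201:215, beta = 2.5, h2 = 0.8),
      trait_spec("chain_child", parent = "chain_parent", chain_coef = 1,
                 chain_noise_sd = 0.5)
    )
  )
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order
#' (simulate -> meta | grm -> greml -> gwas -> pleiotropy -> direction),
#' writing per-stage TSV artifacts, a JSON run summary (seed, thresholds,
#' per-stage counts) and a plain-text log under `config$out_dir`. A failing
#' stage aborts its dependents but the summary still records the stages
#' that completed.
#'
#' @param config a [run_config()].
#' @return list with `summary` (also written as `run_summary.json`),
#'   `artifacts` (named file paths) and the in-memory stage results,
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) ba_stop("`config` must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                paste0(...)), file = log_path, append = TRUE)
  }
  artifacts <- list()
  results <- list()
  summary <- list(seed = config$seed,
                  thresholds = list(gwas_p = config$gwas_p,
                                    greml_alpha = config$greml_alpha,
                                    maf = config$maf,
                                    screen_high = config$screen_high,
                                    screen_low = config$screen_low),
                  stages = list())
  failed <- character(0)
  stage_ok <- function(deps) !any(deps %in% failed)
  run_stage <- function(name, deps, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    if (!stage_ok(deps)) {
      failed <<- c(failed, name)
      msg <- sprintf("stage '%s' skipped: dependency failed (%s)", name,
                     paste(intersect(deps, failed), collapse = ", "))
      log_line(msg)
      summary$stages[[name]] <<- list(status = "skipped", reason = msg)
      return(invisible(NULL))
    }
    missing_dep <- setdiff(deps, c(names(results), config$stages))
    if (length(missing_dep)) {
      ba_stop(sprintf("stage '%s' requires stage(s) %s", name,
                      paste(missing_dep, collapse = ", ")),
              class = "behavarch_dependency_error")
    }
    log_line("stage ", name, " start")
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- c(failed, name)
      log_line("stage ", name, " FAILED: ", conditionMessage(res))
      summary$stages[[name]] <<- list(status = "failed",
                                      error = conditionMessage(res))
    } else {
      results[[name]] <<- res$value
      summary$stages[[name]] <<- c(list(status = "ok"), res$counts)
      for (a in names(res$artifacts)) artifacts[[a]] <<- res$artifacts[[a]]
      log_line("stage ", name, " done")
    }
    invisible(NULL)
  }
  tsv <- function(df, name) {
    p <- file.path(config$out_dir, paste0(name, ".tsv"))
    write.table(format_tsv_numbers(df), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    p
  }

  run_stage("simulate", character(0), function() {
    qc <- config$qtl_config
    if (is.null(qc)) qc <- qtl_sim_config(seed = config$seed)
    pc <- config$panel_config
    if (is.null(pc)) pc <- default_pipeline_panel(config$seed + 1L)
    qtl <- gen_qtl_table(qc)
    panel <- gen_genotypes(pc)
    phen <- gen_phenotypes(panel, pc)
    qtl_path <- file.path(config$out_dir, "qtl_table.csv")
    write_qtl_csv(qtl, qtl_path)
    plink_prefix <- file.path(config$out_dir, "panel")
    write_plink(panel, plink_prefix)
    phen_paths <- vapply(setdiff(names(phen), "line_id"), function(tr) {
      write_phen(setNames(phen[[tr]], phen$line_id),
                 file.path(config$out_dir, paste0(tr, ".phen")))
    }, character(1))
    list(value = list(qtl = qtl, panel = panel, phen = phen,
                      qtl_config = qc, panel_config = pc),
         counts = list(n_qtl = nrow(qtl), n_lines = length(panel$line_ids),
                       n_snps = nrow(panel$snps),
                       seeds = list(qtl = qc$seed, panel = pc$seed)),
         artifacts = c(list(qtl_table = qtl_path, plink = plink_prefix),
                       as.list(phen_paths)))
  })

  run_stage("meta", "simulate", function() {
    qtl <- results$simulate$qtl
    summ <- summarize_by_category(qtl)
    cats <- setdiff(summ$category, "(all)")
    tests <- do.call(rbind, lapply(cats, function(cat) {
      kw <- category_vs_rest_test(qtl, cat)
      pm <- permutation_category_test(qtl, cat, n_perm = config$n_perm_meta,
                                      seed = config$seed)
      data.frame(category = cat, kw_p = kw$p_value,
                 perm_p = pm$p_value, observed_mean = pm$observed_mean,
                 stringsAsFactors = FALSE)
    }))
    div <- divergence_effect_correlation(qtl)
    ct <- cross_type_test(qtl)
    lmm <- fit_lmm_effects(qtl)
    paths <- c(category_summary = tsv(summ, "category_summary"),
               category_tests = tsv(tests, "category_tests"),
               lmm_fixed_effects = tsv(lmm$fixed_effects, "lmm_fixed_effects"))
    list(value = list(summary = summ, tests = tests, divergence = div,
                      cross_type = ct, lmm = lmm),
         counts = list(n_categories = length(cats),
                       divergence_r2 = div$r_squared,
                       cross_type_p = ct$p_value),
         artifacts = as.list(paths))
  })

  run_stage("grm", "simulate", function() {
    panel <- filter_maf(results$simulate$panel, config$maf)
    grm <- grm_decompose(build_grm(panel))
    list(value = list(panel = panel, grm = grm),
         counts = list(n_snps_used = grm$n_snps_used),
         artifacts = list())
  })

  run_stage("greml", c("simulate", "grm"), function() {
    phen <- results$simulate$phen
    traits <- setdiff(names(phen), "line_id")
    fits <- lapply(traits, function(tr) {
      greml_fit(results$grm$grm, setNames(phen[[tr]], phen$line_id))
    })
    names(fits) <- traits
    tab <- do.call(rbind, lapply(traits, function(tr) {
      f <- fits[[tr]]
      data.frame(trait = tr, vg = f$vg, ve = f$ve, h2 = f$h2,
                 se_h2 = f$se_h2, p_value = f$p_value,
                 converged = f$converged, stringsAsFactors = FALSE)
    }))
    kept <- screen_heritable_traits(fits, config$greml_alpha)
    list(value = list(fits = fits, table = tab, heritable = kept),
         counts = list(n_traits = length(traits),
                       n_heritable = length(kept)),
         artifacts = list(greml = tsv(tab, "greml")))
  })

  run_stage("gwas", c("simulate", "grm"), function() {
    panel <- results$grm$panel
    phen <- results$simulate$phen
    traits <- setdiff(names(phen), "line_id")
    scans <- lapply(traits, function(tr) {
      assoc_scan(panel, setNames(phen[[tr]], phen$line_id))
    })
    names(scans) <- traits
    hits <- lapply(scans, significant_hits, threshold = config$gwas_p)
    for (tr in traits) tsv(scans[[tr]], paste0("assoc_", tr))
    list(value = list(scans = scans, hits = hits),
         counts = list(n_traits = length(traits),
                       n_significant_snps = length(unique(unlist(hits)))),
         artifacts = list())
  })

  run_stage("pleiotropy", "gwas", function() {
    hits <- results$gwas$hits
    pm <- build_pleiotropy_matrix(hits)
    em <- build_effect_matrix(results$gwas$scans, hits)
    rho <- tryCatch(trait_correlation_structure(em), error = function(e) NULL)
    paths <- list(effect_matrix = tsv(as.data.frame(unclass(em)), "effect_matrix"))
    list(value = list(pleiotropy = pm, effect_matrix = em, trait_cor = rho),
         counts = list(n_multi_trait_snps = nrow(pm$incidence)),
         artifacts = paths)
  })

  run_stage("direction", "pleiotropy", function() {
    em <- results$pleiotropy$effect_matrix
    pairs <- test_trait_pairs(em, hit_sets = results$gwas$hits,
                              n_perm = config$n_perm_direction,
                              seed = config$seed,
                              high = config$screen_high,
                              low = config$screen_low)
    rep <- adjust_and_report(pairs)
    list(value = rep,
         counts = list(n_pairs_tested = nrow(rep),
                       n_significant = sum(rep$significant)),
         artifacts = list(trait_pairs = tsv(rep, "trait_pairs")))
  })

  summary$failed_stages <- failed
  summary_path <- file.path(config$out_dir, "run_summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA)
  artifacts$run_summary <- summary_path
  artifacts$log <- log_path
  invisible(list(summary = summary, artifacts = artifacts, results = results))
}

# TSV artifacts carry 6 significant digits; the JSON summary keeps full
# precision.
format_tsv_numbers <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- signif(df[[j]], 6)
    }
  }
  df
}

#' Recompute the headline meta-analysis quantities from a compiled QTL CSV
#'
#' Given a compiled QTL table on disk (in the package CSV schema, e.g. a
#' published supplementary table or the output of [write_qtl_csv()]),
#' recomputes the quantities the meta-analysis arm reports: record count,
#' global mean PVE, fraction of loci with PVE < 20, the courtship-vs-rest
#' rank-test p, the permutation p for courtship, the divergence/effect
#' r-squared, the cross-type rank-test p, and the courtship fixed-effect
#' estimate from the linear mixed model.
#'
#' @param path CSV path accepted by [read_qtl_csv()].
#' @param category focal category (default `"courtship"`).
#' @param n_perm,seed permutation settings.
#' @param column_map passed to [read_qtl_csv()].
#' @return named list of the computed quantities.
#' @export
meta_reference_report <- function(path, category = "courtship",
                                  n_perm = 10000L, seed = 1L,
                                  column_map = NULL) {
  qtl <- read_qtl_csv(path, column_map = column_map)
  summ <- summarize_by_category(qtl)
  glob <- summ[summ$category == "(all)", ]
  kw <- category_vs_rest_test(qtl, category)
  pm <- permutation_category_test(qtl, category, n_perm = n_perm, seed = seed)
  div <- divergence_effect_correlation(qtl)
  ct <- cross_type_test(qtl)
  lmm <- fit_lmm_effects(qtl)
  fe <- lmm$fixed_effects
  focal_row <- grepl(category, fe$term, fixed = TRUE)
  list(n_records = nrow(qtl),
       mean_pve = glob$mean_pve,
       fraction_pve_below_20 = glob$fraction_pve_below_20,
       category_kw_p = kw$p_value,
       category_perm_p = pm$p_value,
       divergence_r2 = div$r_squared,
       cross_type_p = ct$p_value,
       category_lmm_estimate = if (any(focal_row)) fe$estimate[focal_row][1] else NA_real_,
       category_lmm_se = if (any(focal_row)) fe$se[focal_row][1] else NA_real_)
}
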