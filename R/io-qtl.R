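# QTL table CSV schema. On-disk column names (left) map to the in-memory
# record fields (right); the reader accepts a user-supplied column_map for
# tables with different headers.
qtl_csv_schema <- c(
  study_id = "study_id", species_a = "species_a", species_b = "species_b",
  taxon_class = "taxon_class", category = "behavioral_category",
  trait = "trait_name", pve = "effect_size_pve", lod = "lod",
  neglog10_p = "neglog10_p", sample_size = "sample_size",
  generations = "generations_diverged", years = "years_diverged",
  cross_type = "cross_type", chrom = "chrom", pos = "pos"
)

#' Read a compiled QTL table from CSV
#'
#' Schema-validated reader for compiled QTL meta-tables. Rows violating the
#' record invariants (PVE outside (0, 100], nonpositive sample size,
#' neither LOD nor -log10 P present, cross type inconsistent with the
#' species pair) are rejected with line-numbered diagnostics in a warning
#' and returned in `attr(, "rejected")`.
#'
#' @param path CSV file with a header.
#' @param column_map named character vector mapping on-disk column names to
#'   the canonical schema names (`names()` = file columns, values =
#'   canonical names such as `pve`, `category`, ...). Identity by default.
#' @return a `qtl_table` data.frame (see [gen_qtl_table()] for columns).
#' @export
read_qtl_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) ba_stop(sprintf("no such file: %s", path),
                                  class = "behavarch_io_error")
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    hit <- names(raw) %in% names(column_map)
    names(raw)[hit] <- unname(column_map[names(raw)[hit]])
  }
  mandatory <- c("study_id", "category", "pve", "sample_size", "cross_type")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    ba_stop(paste("missing mandatory columns:",
                  paste(missing_cols, collapse = ", ")),
            class = "behavarch_schema_error")
  }
  for (col in names(qtl_csv_schema)) if (is.null(raw[[col]])) raw[[col]] <- NA
  out <- setNames(raw[names(qtl_csv_schema)], unname(qtl_csv_schema))

  bad <- rep(FALSE, nrow(out))
  why <- character(nrow(out))
  flag <- function(cond, reason) {
    cond <- !is.na(cond) & cond
    why[cond & !bad] <<- reason
    bad <<- bad | cond
  }
  flag(!is.finite(out$effect_size_pve) | out$effect_size_pve <= 0 |
         out$effect_size_pve > 100, "PVE outside (0,100]")
  flag(is.na(out$sample_size) | out$sample_size <= 0,
       "nonpositive sample size")
  flag(is.na(out$lod) & is.na(out$neglog10_p),
       "neither LOD nor -log10 P present")
  flag(!out$cross_type %in% c("intraspecific", "interspecific"),
       "unknown cross_type")
  both_sp <- !is.na(out$species_a) & !is.na(out$species_b)
  flag(both_sp & (out$cross_type == "interspecific") !=
         (out$species_a != out$species_b),
       "cross_type inconsistent with species pair")

  if (any(bad)) {
    lines <- which(bad) + 1L  # header is line 1
    warning(sprintf("rejected %d row(s): %s", sum(bad),
                    paste(sprintf("line %d (%s)", head(lines, 10L),
                                  head(why[bad], 10L)), collapse = "; ")))
  }
  rejected <- out[bad, , drop = FALSE]
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("qtl_table", "data.frame")
  attr(out, "rejected") <- rejected
  out
}

#' Write a QTL table to the package CSV schema
#'
#' @param records a `qtl_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qtl_csv <- function(records, path) {
  inv <- qtl_csv_schema
  out <- setNames(as.data.frame(records)[unname(inv)], names(inv))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate replicate phenotype measurements per line
#'
#' Per-line mean across replicate measurements for each trait; missing
#' replicates are dropped from the mean and the replicate count is recorded.
#'
#' @param measures long-format data.frame with columns `line_id`, `trait`,
#'   `value` (one row per replicate measurement).
#' @return a wide `phenotype_table` (column `line_id` plus one column per
#'   trait) with `attr(, "aggregation")` describing the rule and
#'   `attr(, "n_replicates")` the per-cell counts.
#' @export
aggregate_replicates <- function(measures) {
  need <- c("line_id", "trait", "value")
  if (!all(need %in% names(measures))) {
    ba_stop("measures must have columns line_id, trait, value",
            class = "behavarch_schema_error")
  }
  mtab <- aggregate(value ~ line_id + trait, data = measures, FUN = mean,
                    na.rm = TRUE, na.action = stats::na.pass)
  ntab <- aggregate(value ~ line_id + trait, data = measures,
                    FUN = function(v) sum(!is.na(v)),
                    na.action = stats::na.pass)
  lines <- sort(unique(measures$line_id))
  traits <- sort(unique(measures$trait))
  out <- data.frame(line_id = lines, stringsAsFactors = FALSE)
  counts <- matrix(0L, length(lines), length(traits),
                   dimnames = list(lines, traits))
  for (tr in traits) {
    sub <- mtab[mtab$trait == tr, ]
    out[[tr]] <- sub$value[match(lines, sub$line_id)]
    nsub <- ntab[ntab$trait == tr, ]
    counts[, tr] <- nsub$value[match(lines, nsub$line_id)]
  }
  out[is.na(out)] <- NA
  class(out) <- c("phenotype_table", "data.frame")
  attr(out, "aggregation") <- "mean of non-missing replicates"
  attr(out, "n_replicates") <- counts
  out
}
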