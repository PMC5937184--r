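# plink bed/bim/fam codec. bed layout: magic bytes 0x6c 0x1b, mode byte
# 0x01 (SNP-major), then ceil(n/4) bytes per SNP, two bits per line packed
# low-to-high within each byte: 00 = hom A1 (dosage 2), 01 = missing,
# 10 = het (dosage 1), 11 = hom A2 (dosage 0). Dosage counts the A1
# (minor-labelled) allele.

bed_code_to_dosage <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
dosage_to_bed_code <- function(d) {
  ifelse(is.na(d), 1L, ifelse(d == 2, 0L, ifelse(d == 1, 2L, 3L)))
}

#' Read genotypes from plink bed/bim/fam or VCF
#'
#' @param path for `format = "bed"`, the fileset prefix (or the `.bed`
#'   path); `.bim` and `.fam` must sit alongside. For `format = "vcf"`, a
#'   (possibly gzipped) VCF with diploid GT fields; dosage is the count of
#'   the alternate allele.
#' @param format `"bed"` (default) or `"vcf"`.
#' @return a `genotype_panel`.
#' @export
read_genotypes <- function(path, format = c("bed", "vcf")) {
  format <- match.arg(format)
  if (format == "bed") read_plink_bed(path) else read_vcf_panel(path)
}

read_plink_bed <- function(prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  if (!all(file.exists(paths))) {
    ba_stop(sprintf("missing plink fileset component(s): %s",
                    paste(paths[!file.exists(paths)], collapse = ", ")),
            class = "behavarch_io_error")
  }
  bim <- read.table(paths[2], stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam <- read.table(paths[3], stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    ba_stop("bad bed magic bytes", class = "behavarch_format_error")
  }
  if (raw[3] != as.raw(0x01)) {
    ba_stop("only SNP-major bed files are supported",
            class = "behavarch_format_error")
  }
  bps <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bps * m) {
    ba_stop("bed payload size inconsistent with bim/fam",
            class = "behavarch_format_error")
  }
  ints <- as.integer(body)
  # unpack the four 2-bit fields of every byte, then drop padding
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  codes <- matrix(codes, nrow = 4L * bps)  # (4*bps) x m
  codes <- codes[seq_len(n), , drop = FALSE]
  X <- matrix(bed_code_to_dosage[as.character(codes)], n, m)
  line_ids <- as.character(fam[[2]])
  snps <- data.frame(id = bim$id, chrom = as.character(bim$chrom),
                     pos = bim$pos, a1 = bim$a1, a2 = bim$a2,
                     stringsAsFactors = FALSE)
  rownames(X) <- line_ids
  colnames(X) <- snps$id
  new_genotype_panel(line_ids, snps, X)
}

#' Write a genotype panel as plink bed/bim/fam
#'
#' Round-trips bit-exactly with [read_genotypes()].
#'
#' @param panel a `genotype_panel`.
#' @param prefix output fileset prefix.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  if (!inherits(panel, "genotype_panel")) ba_stop("`panel` must be a genotype_panel")
  X <- panel$X
  n <- nrow(X); m <- ncol(X)
  bim <- data.frame(chrom = panel$snps$chrom, id = panel$snps$id, cm = 0,
                    pos = panel$snps$pos, a1 = panel$snps$a1,
                    a2 = panel$snps$a2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = panel$line_ids, iid = panel$line_ids,
                    pat = 0, mat = 0, sex = 0, phen = -9)
  write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bps <- ceiling(n / 4)
  codes <- matrix(1L, 4L * bps, m)  # pad with the missing code, masked below
  codes[seq_len(n), ] <- dosage_to_bed_code(X)
  codes[seq_len(4L * bps) > n, ] <- 0L  # plink pads with zero bits
  grp <- matrix(codes, nrow = 4L)
  bytes <- as.raw(grp[1, ] + 4L * grp[2, ] + 16L * grp[3, ] + 64L * grp[4, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  invisible(prefix)
}

read_vcf_panel <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    ba_stop("reading VCF requires the vcfR package",
            class = "behavarch_io_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fixed <- vcfR::getFIX(v)
  # collapse GT to alternate-allele dosage; any non-diploid call errors
  dose_one <- function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
    parts <- strsplit(g, "[/|]")[[1]]
    if (length(parts) != 2L) {
      ba_stop(sprintf("non-diploid genotype '%s'", g),
              class = "behavarch_format_error")
    }
    if (any(parts == ".")) return(NA_real_)
    sum(as.numeric(parts) > 0)
  }
  # apply over variants returns a samples x variants matrix
  X <- apply(gt, 1L, function(row) vapply(row, dose_one, numeric(1)))
  if (is.null(dim(X))) X <- matrix(X, nrow = ncol(gt))
  ids <- fixed[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fixed[is.na(ids) | ids == ".", "CHROM"],
                                         ":", fixed[is.na(ids) | ids == ".", "POS"])
  snps <- data.frame(id = ids, chrom = fixed[, "CHROM"],
                     pos = as.integer(fixed[, "POS"]),
                     a1 = fixed[, "ALT"], a2 = fixed[, "REF"],
                     stringsAsFactors = FALSE)
  line_ids <- colnames(gt)
  rownames(X) <- line_ids
  colnames(X) <- snps$id
  new_genotype_panel(line_ids, snps, X)
}

#' Read a .phen phenotype file
#'
#' Whitespace-delimited (family id, individual id, value); `NA` and `-9`
#' map to missing.
#'
#' @param path file path.
#' @return named numeric vector keyed by individual id.
#' @export
read_phen <- function(path) {
  if (!file.exists(path)) ba_stop(sprintf("no such file: %s", path),
                                  class = "behavarch_io_error")
  tab <- read.table(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) ba_stop(".phen needs >= 3 columns",
                              class = "behavarch_format_error")
  vals_raw <- as.character(tab[[3]])   # "NA" already parsed to NA upstream
  num <- suppressWarnings(as.numeric(vals_raw))
  bad <- is.na(num) & !is.na(vals_raw) & !vals_raw %in% c("NA", "-9", "nan")
  if (any(bad)) {
    ba_stop(sprintf("non-numeric phenotype value at line(s) %s",
                    paste(head(which(bad), 5L), collapse = ", ")),
            class = "behavarch_parse_error")
  }
  num[vals_raw == "-9"] <- NA_real_
  ids <- as.character(tab[[2]])
  if (anyDuplicated(ids)) {
    ba_stop(sprintf("duplicate individual id(s): %s",
                    paste(head(unique(ids[duplicated(ids)]), 5L), collapse = ", ")),
            class = "behavarch_parse_error")
  }
  setNames(num, ids)
}

#' Write a .phen phenotype file
#'
#' @param values named numeric vector (names = line ids; used for both
#'   family and individual id columns). Missing written as `-9`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phen <- function(values, path) {
  if (is.null(names(values))) ba_stop("`values` must be named by line id")
  out <- data.frame(fid = names(values), iid = names(values),
                    value = ifelse(is.na(values), "-9",
                                   format(values, digits = 17, trim = TRUE)))
  write.table(out, path, sep = " ", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
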