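#' Construct a genotype dosage matrix
#'
#' Container for individual-level dosages: an individuals-by-variants
#' matrix of expected counted-allele counts in \[0, 2\] (fractional after
#' imputation), with per-variant metadata.  The counted allele is the
#' allele whose dosage is stored (VCF ALT; PLINK A1).
#'
#' @param samples character vector of sample ids.
#' @param variants data frame with columns `snp_id`, `chrom`, `pos`,
#'   `counted_allele`, `other_allele` and optionally `impute_score`
#'   (a \[0,1\] imputation quality; `NA` when unknown).
#' @param dosages numeric matrix, `length(samples)` rows by
#'   `nrow(variants)` columns; `NA` encodes missing.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, variants, dosages) {
  samples <- as.character(samples)
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(samples) || ncol(dosages) != nrow(variants)) {
    stop_input("dosage dimensions inconsistent with samples/variants")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop_input("dosages must lie in [0, 2] or be NA")
  }
  if (is.null(variants$impute_score)) variants$impute_score <- NA_real_
  variants$snp_id <- as.character(variants$snp_id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$counted_allele <- norm_allele(variants$counted_allele)
  variants$other_allele <- norm_allele(variants$other_allele)
  rownames(dosages) <- samples
  colnames(dosages) <- variants$snp_id
  structure(list(samples = samples, variants = variants, dosages = dosages),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants\n",
              length(x$samples), nrow(x$variants)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Per-variant missingness fractions
#' @param gm a `genotype_matrix`.
#' @export
variant_missingness <- function(gm) {
  colMeans(is.na(gm$dosages))
}

#' Read genotypes from VCF or PLINK files
#'
#' For VCF, the `DS` FORMAT field (posterior dosage of the ALT allele)
#' is used when present and `GT` otherwise (dosage = ALT-allele count);
#' the counted allele is ALT.  For PLINK bed/bim/fam triples, `path`
#' is the file prefix and the counted allele is bim column 5 (A1).
#' Per-variant imputation quality is read from an `INFO` key named in
#' `impute_key` (VCF only) when present.
#'
#' @param path VCF path, or PLINK prefix (without extension).
#' @param format `"vcf"` or `"plink"`.
#' @param impute_key INFO key holding the imputation quality (VCF).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "plink"),
                           impute_key = "INFO_SCORE") {
  format <- match.arg(format)
  if (format == "vcf") read_genotypes_vcf(path, impute_key)
  else read_genotypes_plink(path)
}

read_genotypes_vcf <- function(path, impute_key = "INFO_SCORE") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_m <- vcfR::getFIX(v)
  if (is.null(dim(fix_m))) fix_m <- t(fix_m)    # single-variant file
  fix <- as.data.frame(fix_m, stringsAsFactors = FALSE)
  info <- vcfR::extract.info(v, element = impute_key, as.numeric = TRUE)
  if (all(is.na(info))) info <- NA_real_
  variants <- data.frame(
    snp_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    counted_allele = fix$ALT, other_allele = fix$REF,
    impute_score = info, stringsAsFactors = FALSE
  )
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else if ("GT" %in% fmt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      if (is.na(g)) return(NA_real_)
      alleles <- strsplit(g, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_real_)
      sum(alleles == "1")
    }
    ds <- apply(gt, c(1, 2), count_alt)
  } else {
    stop_input("VCF has neither DS nor GT FORMAT fields: ", path)
  }
  genotype_matrix(colnames(ds), variants, t(ds))
}

#' Write a genotype matrix as a dosage VCF
#'
#' Emits a minimal VCFv4.2 file with the counted allele as ALT and a
#' `DS` FORMAT field; per-variant imputation quality (when present) is
#' written to the INFO key named by `impute_key`.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path (plain text).
#' @param impute_key INFO key for the imputation quality.
#' @export
write_genotypes_vcf <- function(gm, path, impute_key = "INFO_SCORE") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Imputation quality\">",
            impute_key),
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  ), con)
  vt <- gm$variants
  for (j in seq_len(nrow(vt))) {
    info <- if (is.na(vt$impute_score[j])) "." else
      sprintf("%s=%.6g", impute_key, vt$impute_score[j])
    ds <- gm$dosages[, j]
    ds_str <- ifelse(is.na(ds), ".", formatC(ds, format = "g", digits = 8))
    writeLines(paste(c(vt$chrom[j], vt$pos[j], vt$snp_id[j],
                       vt$other_allele[j], vt$counted_allele[j],
                       ".", "PASS", info, "DS", ds_str),
                     collapse = "\t"), con)
  }
  invisible(path)
}

# --- PLINK bed/bim/fam codec ------------------------------------------------
# Minimal SNP-major .bed reader/writer (magic 0x6c 0x1b, mode 0x01).
# Two bits per individual: 00 = 2 copies of A1, 01 = missing,
# 10 = 1 copy of A1, 11 = 0 copies.  Dosage stored is the A1 count.

read_genotypes_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop_input("missing PLINK file: ", f)
  }
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  samples <- as.character(fam_df[[2]])
  n <- length(samples)
  m <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop_input("not a PLINK bed file: ", bed)
  }
  if (raw[3] != as.raw(0x01)) stop_input("only SNP-major bed supported")
  bpv <- ceiling(n / 4)
  if (length(raw) - 3L != bpv * m) {
    stop_input("truncated bed file: ", bed)
  }
  # decode lookup: byte -> 4 dosages
  two_bits <- function(byte) {
    v <- as.integer(byte)
    c(bitwAnd(v, 3L), bitwAnd(bitwShiftR(v, 2L), 3L),
      bitwAnd(bitwShiftR(v, 4L), 3L), bitwAnd(bitwShiftR(v, 6L), 3L))
  }
  code_to_dosage <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  lut <- vapply(0:255, function(b) code_to_dosage[as.character(two_bits(as.raw(b)))],
                numeric(4))
  body <- as.integer(raw[-(1:3)]) + 1L
  dos <- matrix(NA_real_, nrow = n, ncol = m)
  idx <- seq_len(n)
  for (j in seq_len(m)) {
    bytes <- body[((j - 1L) * bpv + 1L):(j * bpv)]
    col <- as.vector(lut[, bytes])[idx]
    dos[, j] <- col
  }
  variants <- data.frame(
    snp_id = as.character(bim_df[[2]]), chrom = as.character(bim_df[[1]]),
    pos = as.integer(bim_df[[4]]),
    counted_allele = as.character(bim_df[[5]]),
    other_allele = as.character(bim_df[[6]]),
    stringsAsFactors = FALSE
  )
  genotype_matrix(samples, variants, dos)
}

#' Write a genotype matrix as a PLINK bed/bim/fam triple
#'
#' Dosages are rounded to the nearest hard genotype (0/1/2 copies of the
#' counted allele, written as bim A1); `NA` becomes the missing code.
#'
#' @param gm a `genotype_matrix`.
#' @param prefix output path prefix (writes `prefix.bed/.bim/.fam`).
#' @param phenotypes optional phenotype table whose `case_status`
#'   fills fam column 6 (1 = control, 2 = case).
#' @export
write_genotypes_plink <- function(gm, prefix, phenotypes = NULL) {
  n <- length(gm$samples)
  m <- nrow(gm$variants)
  pheno <- rep(-9L, n)
  sex <- rep(0L, n)
  if (!is.null(phenotypes)) {
    i <- match(gm$samples, phenotypes$sample_id)
    pheno <- ifelse(is.na(i), -9L, phenotypes$case_status[i] + 1L)
    if (!is.null(phenotypes$sex)) {
      sex <- ifelse(is.na(i), 0L, as.integer(phenotypes$sex[i]))
    }
  }
  fam <- data.frame(gm$samples, gm$samples, 0L, 0L, sex, pheno)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- data.frame(gm$variants$chrom, gm$variants$snp_id, 0,
                    gm$variants$pos, gm$variants$counted_allele,
                    gm$variants$other_allele)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  # dosage -> 2-bit codes, 4 individuals per byte, SNP-major
  bpv <- ceiling(n / 4)
  code_of <- function(d) {
    ifelse(is.na(d), 1L, c(3L, 2L, 0L)[round(d) + 1L])
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- bpv * 4L - n
  for (j in seq_len(m)) {
    codes <- c(code_of(gm$dosages[, j]), rep(0L, pad))
    cm <- matrix(codes, nrow = 4)
    bytes <- cm[1, ] + cm[2, ] * 4L + cm[3, ] * 16L + cm[4, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Variant-level quality-control filter
#'
#' Retains variants with missingness strictly below `max_missing` and
#' (when an imputation score is available) imputation quality strictly
#' above `min_impute`; a variant sitting exactly at either threshold is
#' removed.  Variants without an imputation score pass that criterion.
#'
#' @param gm a `genotype_matrix`.
#' @param max_missing maximum tolerated missing fraction (exclusive).
#' @param min_impute minimum imputation quality (exclusive).
#' @return filtered `genotype_matrix`; removal counts are reported.
#' @export
qc_filter_variants <- function(gm, max_missing = 0.02, min_impute = 0.8) {
  check_prob(max_missing, "max_missing")
  check_prob(min_impute, "min_impute")
  miss <- variant_missingness(gm)
  imp <- gm$variants$impute_score
  keep_miss <- miss < max_missing
  keep_imp <- is.na(imp) | imp > min_impute
  keep <- keep_miss & keep_imp
  n_rm <- sum(!keep)
  if (n_rm > 0) {
    pes_log("qc_filter_variants: removed %d variant(s) (%d high-missing, %d low-imputation)",
            n_rm, sum(!keep_miss), sum(!keep_imp))
  }
  if (!any(keep)) {
    warning("qc_filter_variants: all variants removed", call. = FALSE)
  }
  genotype_matrix(gm$samples, gm$variants[keep, , drop = FALSE],
                  gm$dosages[, keep, drop = FALSE])
}

#' Mean-impute missing dosages per variant
#'
#' Missing entries in each retained variant are replaced by the
#' variant's observed mean dosage, keeping score length constant
#' across individuals (the PLINK scoring convention).
#'
#' @param gm a `genotype_matrix`.
#' @export
mean_impute_dosages <- function(gm) {
  d <- gm$dosages
  nas <- which(is.na(d), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    mu <- colMeans(d, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    d[nas] <- mu[nas[, 2]]
    gm$dosages <- d
  }
  gm
}
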