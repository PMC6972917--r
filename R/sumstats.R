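#' Read GWAS summary statistics
#'
#' Reads a whitespace- or tab-delimited summary-statistics file with a
#' header and returns a validated data frame of one row per variant.
#' Effect sizes may be supplied either as additive betas or as odds
#' ratios; odds ratios are log-transformed at read time so all
#' downstream arithmetic works on the beta scale.
#'
#' Rows with a P value outside (0, 1], or with a missing/identical
#' allele pair, are dropped and the dropped count is reported.
#'
#' @param path path to the delimited file (header required).
#' @param column_map named character vector (or list) mapping the
#'   canonical field names `snp_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `pvalue` and one of `beta` or `or` to the column
#'   names present in the file.
#' @param sep field separator passed to [utils::read.table()]; the
#'   default `""` accepts any whitespace.
#' @return a `data.frame` with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `pvalue`, with attribute
#'   `n_dropped` counting invalid rows removed.
#' @export
read_summary_stats <- function(path, column_map = NULL, sep = "") {
  column_map <- as.list(column_map %||% list(
    snp_id = "SNP", chrom = "CHR", pos = "BP",
    effect_allele = "A1", other_allele = "A2",
    beta = "BETA", pvalue = "P"
  ))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele", "pvalue")
  for (f in need) {
    cn <- column_map[[f]]
    if (is.null(cn) || !cn %in% names(raw)) {
      stop_input("mandatory column '", f, "' (mapped to '",
                 cn %||% "<unset>", "') not found in ", path)
    }
  }
  has_beta <- !is.null(column_map$beta) && column_map$beta %in% names(raw)
  has_or <- !is.null(column_map$or) && column_map$or %in% names(raw)
  if (!has_beta && !has_or) {
    stop_input("column_map must name a 'beta' or 'or' column present in the file")
  }
  beta <- if (has_beta) as.numeric(raw[[column_map$beta]]) else
    log(as.numeric(raw[[column_map$or]]))
  ss <- data.frame(
    snp_id = as.character(raw[[column_map$snp_id]]),
    chrom = as.character(raw[[column_map$chrom]]),
    pos = as.integer(raw[[column_map$pos]]),
    effect_allele = norm_allele(raw[[column_map$effect_allele]]),
    other_allele = norm_allele(raw[[column_map$other_allele]]),
    beta = beta,
    pvalue = as.numeric(raw[[column_map$pvalue]]),
    stringsAsFactors = FALSE
  )
  ok <- !is.na(ss$pvalue) & ss$pvalue > 0 & ss$pvalue <= 1 &
    !is.na(ss$beta) & is.finite(ss$beta) &
    nzchar(ss$effect_allele) & nzchar(ss$other_allele) &
    ss$effect_allele != ss$other_allele &
    !is.na(ss$pos) & ss$pos >= 1L
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    pes_log("read_summary_stats: dropped %d invalid row(s)", n_dropped)
  }
  ss <- ss[ok, , drop = FALSE]
  if (nrow(ss) == 0L) stop_input("no valid summary-statistic rows in ", path)
  rownames(ss) <- NULL
  attr(ss, "n_dropped") <- n_dropped
  ss
}

#' Write summary statistics in the package's canonical layout
#'
#' @param sumstats data frame as returned by [read_summary_stats()].
#' @param path output path (tab-delimited, with header).
#' @export
write_summary_stats <- function(sumstats, path) {
  cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "beta", "pvalue")
  out <- sumstats[, cols]
  names(out) <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "P")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Retain variants below a P-value threshold
#'
#' Keeps records with `pvalue < p_t` (strictly below the threshold, so a
#' variant sitting exactly at the ceiling is excluded); `p_t = 1`
#' retains every record ("all SNPs").
#'
#' @param sumstats summary-statistics data frame.
#' @param p_t P-value ceiling in (0, 1].
#' @export
subset_by_threshold <- function(sumstats, p_t) {
  check_prob(p_t, "p_t", open_left = TRUE)
  if (p_t == 1) return(sumstats)
  sumstats[sumstats$pvalue < p_t, , drop = FALSE]
}

#' P-value threshold grid for the gene analysis
#'
#' Default grid: all SNPs (1.0) then 0.5, 0.05, 0.005, spanning two
#' orders of magnitude around nominal significance.
#'
#' @param thresholds numeric vector in (0,1]; after a leading 1.0 the
#'   values must be strictly decreasing.
#' @export
threshold_config <- function(thresholds = c(1.0, 0.5, 0.05, 0.005)) {
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop_input("thresholds must lie in (0,1]")
  }
  tail_part <- thresholds[thresholds < 1]
  if (any(diff(tail_part) >= 0)) {
    stop_input("thresholds must be strictly decreasing after the leading 1.0")
  }
  thresholds
}
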