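#' Harmonise summary-statistic effect alleles with genotype dosages
#'
#' Aligns GWAS effect sizes to the allele counted in a genotype matrix
#' so that scores can be evaluated directly on dosages.  Variants are
#' joined on (chrom, pos) with allele-pair matching by default; join on
#' `snp_id` is opt-in since ids drift across genome builds.
#'
#' Alignment rules: when the counted allele equals the effect allele the
#' beta is used as-is; when it equals the other allele the beta is
#' sign-flipped; strand-ambiguous palindromic pairs (A/T, C/G) are
#' dropped under the default policy, as are variants whose allele pairs
#' do not match or that duplicate a position with conflicting alleles.
#'
#' @param sumstats summary-statistics data frame.
#' @param gm a [genotype_matrix()].
#' @param join `"position"` (default: chrom, pos + allele pair) or
#'   `"snp_id"`.
#' @param drop_palindromic drop A/T and C/G variants (default TRUE).
#' @return data frame with one row per aligned variant: `snp_id`
#'   (genotype id), `col` (column index into `gm$dosages`), `beta`
#'   (aligned to the counted allele), `pvalue`, `chrom`, `pos`,
#'   `flipped`; attribute `n_dropped` lists drop reasons.
#' @export
harmonise_alleles <- function(sumstats, gm, join = c("position", "snp_id"),
                              drop_palindromic = TRUE) {
  join <- match.arg(join)
  vt <- gm$variants
  if (join == "position") {
    key_ss <- sprintf("%s:%d", sumstats$chrom, as.integer(sumstats$pos))
    key_gm <- sprintf("%s:%d", vt$chrom, as.integer(vt$pos))
  } else {
    key_ss <- sumstats$snp_id
    key_gm <- vt$snp_id
  }
  orig_idx <- seq_len(nrow(vt))
  dup_gm <- duplicated(key_gm) | duplicated(key_gm, fromLast = TRUE)
  n_dup <- 0L
  if (any(dup_gm)) {
    # duplicated join keys (possibly conflicting alleles): drop them all
    n_dup <- sum(dup_gm)
    vt <- vt[!dup_gm, , drop = FALSE]
    key_gm <- key_gm[!dup_gm]
    orig_idx <- orig_idx[!dup_gm]
  }
  idx <- match(key_ss, key_gm)
  matched <- !is.na(idx)
  n_unmatched <- sum(!matched)
  ss <- sumstats[matched, , drop = FALSE]
  gcol <- orig_idx[idx[matched]]
  gv <- gm$variants[gcol, , drop = FALSE]

  ea <- ss$effect_allele; oa <- ss$other_allele
  ca <- gv$counted_allele; na_ <- gv$other_allele
  same <- ca == ea & na_ == oa
  flip <- ca == oa & na_ == ea
  palin <- is_palindromic(ea, oa)
  keep <- (same | flip) & !(drop_palindromic & palin)
  n_palin <- sum((same | flip) & drop_palindromic & palin)
  n_mismatch <- sum(!(same | flip))
  out <- data.frame(
    snp_id = gv$snp_id[keep],
    col = gcol[keep],
    beta = ifelse(flip[keep], -ss$beta[keep], ss$beta[keep]),
    pvalue = ss$pvalue[keep],
    chrom = gv$chrom[keep],
    pos = gv$pos[keep],
    flipped = flip[keep],
    stringsAsFactors = FALSE
  )
  dropped <- c(unmatched = n_unmatched, palindromic = n_palin,
               allele_mismatch = n_mismatch, duplicated_key = n_dup)
  if (sum(dropped) > 0) {
    pes_log("harmonise_alleles: dropped %d variant(s) (%s)", sum(dropped),
            paste(names(dropped), dropped, sep = "=", collapse = ", "))
  }
  attr(out, "n_dropped") <- dropped
  out
}
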