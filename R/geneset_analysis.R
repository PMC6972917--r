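#' Competitive gene-set association test
#'
#' Tests whether genes in a set are more strongly trait-associated than
#' all other tested genes, at one P threshold.  The gene Z scores are
#' regressed by ordinary least squares on a set-membership indicator
#' plus gene-level confounders (intercept, SNP count and its log); the
#' reported P value is one-sided for a positive set coefficient
#' (enrichment only), from the t distribution on the residual degrees
#' of freedom.
#'
#' @param gene_results gene-analysis rows at a single threshold
#'   (columns `gene_id`, `gene_z`, `n_snps`).
#' @param set a [gene_set()] (or character vector of gene ids).
#' @param p_threshold optional label carried into the result.
#' @return one-row data frame: `set_name`, `p_threshold`, `beta`, `se`,
#'   `pvalue`, `n_genes_in_set_tested`.
#' @export
competitive_set_test <- function(gene_results, set, p_threshold = NA_real_) {
  genes <- if (inherits(set, "gene_set")) set$genes else as.character(set)
  set_name <- if (inherits(set, "gene_set")) set$name else NA_character_
  member <- as.numeric(gene_results$gene_id %in% genes)
  n_in <- sum(member == 1)
  n_out <- sum(member == 0)
  if (n_in < 2L || n_out < 2L) {
    stop_input("competitive_set_test: need >=2 genes inside and outside the set (have ",
               n_in, "/", n_out, ")")
  }
  if (stats::var(gene_results$gene_z) == 0) {
    # constant response: no evidence either way
    return(data.frame(set_name = set_name, p_threshold = p_threshold,
                      beta = 0, se = 0, pvalue = 0.5,
                      n_genes_in_set_tested = n_in,
                      stringsAsFactors = FALSE))
  }
  m <- gene_results$n_snps
  x <- cbind(1, member, m, log(m))
  fit <- stats::lm.fit(x, gene_results$gene_z)
  df <- length(gene_results$gene_z) - fit$rank
  if (df < 1) {
    stop_input("competitive_set_test: no residual degrees of freedom")
  }
  rss <- sum(fit$residuals^2)
  # (X'X)^-1 diagonal for the member column via the QR decomposition
  xtx_inv <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
  # lm.fit pivots columns; locate the member coefficient
  pos <- which(fit$qr$pivot == 2L)
  beta <- unname(fit$coefficients[2])
  sigma2 <- rss / df
  se <- sqrt(sigma2 * xtx_inv[pos, pos])
  if (!is.finite(se) || se == 0) {
    # zero residual variance: constant response (no evidence either way)
    # or an exactly membership-determined response
    tstat <- if (abs(beta) < 1e-12) 0 else sign(beta) * Inf
  } else {
    tstat <- beta / se
  }
  pval <- stats::pt(tstat, df = df, lower.tail = FALSE)
  data.frame(set_name = set_name, p_threshold = p_threshold,
             beta = ifelse(is.finite(beta), beta, 0), se = se,
             pvalue = pval, n_genes_in_set_tested = n_in,
             stringsAsFactors = FALSE)
}

#' Competitive association of druggable pathways at every threshold
#'
#' One competitive test per (set, threshold) pair; pairs whose design
#' is degenerate (set covering all or almost no tested genes) are
#' skipped with a log entry.
#'
#' @param gene_results full gene-analysis table (all thresholds).
#' @param druggable_sets retained sets from [flag_druggable()].
#' @return data frame of set results.
#' @export
run_set_analysis <- function(gene_results, druggable_sets) {
  thresholds <- unique(gene_results$p_threshold)
  out <- list()
  n_skipped <- 0L
  for (p_t in thresholds) {
    block <- gene_results[gene_results$p_threshold == p_t, , drop = FALSE]
    for (s in druggable_sets) {
      res <- tryCatch(competitive_set_test(block, s, p_threshold = p_t),
                      error = function(e) NULL)
      if (is.null(res)) {
        n_skipped <- n_skipped + 1L
        next
      }
      out[[length(out) + 1L]] <- res
    }
  }
  if (n_skipped > 0) {
    pes_log("run_set_analysis: skipped %d degenerate (set, threshold) pair(s)",
            n_skipped)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select candidate pathways for pharmagenic scoring
#'
#' Retains sets associated below the nominal threshold (strict
#' `pvalue < alpha`) at one or more P thresholds.  When a set is
#' associated at several thresholds the most significant one is
#' chosen; exact ties go to the more stringent (smaller) threshold.
#'
#' @param set_results table from [run_set_analysis()].
#' @param sets the gene-set collection (named list), used to attach
#'   genes and druggable genes to each candidate.
#' @param alpha selection threshold (default 0.001).
#' @return data frame of candidates: `set_name`, `p_threshold`,
#'   `pvalue`, `beta`, `se`, plus list-columns `genes` and
#'   `druggable_genes`.
#' @export
select_candidates <- function(set_results, sets = NULL, alpha = 0.001) {
  if (nrow(set_results) == 0L) stop_input("select_candidates: empty set_results")
  hits <- set_results[set_results$pvalue < alpha, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(set_name = character(0), p_threshold = numeric(0),
                      pvalue = numeric(0), beta = numeric(0),
                      se = numeric(0), stringsAsFactors = FALSE))
  }
  # per set: smallest P; ties -> more stringent (smaller) threshold
  ord <- order(hits$set_name, hits$pvalue, hits$p_threshold)
  hits <- hits[ord, , drop = FALSE]
  best <- hits[!duplicated(hits$set_name), , drop = FALSE]
  best <- best[order(best$pvalue), , drop = FALSE]
  rownames(best) <- NULL
  if (!is.null(sets)) {
    best$genes <- I(lapply(best$set_name, function(nm) sets[[nm]]$genes))
    best$druggable_genes <- I(lapply(best$set_name,
                                     function(nm) sets[[nm]]$druggable_genes))
  }
  best
}
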