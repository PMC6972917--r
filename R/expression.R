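#' Test score effects on the expression of pathway genes
#'
#' For each candidate pathway, regresses the expression of every
#' pathway gene available in the expression matrix on the pathway's
#' score, with age, sex and the genome-wide score as covariates:
#' `expression ~ PES + age + sex + PRS_TOTAL`.  Reports the
#' standardised coefficient `t = beta/se` with a two-sided P from the
#' t distribution on the residual degrees of freedom, and a BH q-value
#' computed within each pathway (so the correction matches the number
#' of genes tested in that set).  Genes appearing in several pathways
#' are tested once per pathway.
#'
#' @param scores score matrix (individuals by scores; must contain one
#'   column per pathway tested and a `PRS_TOTAL` column unless
#'   `covariates` overrides).
#' @param expression genes-by-individuals numeric matrix.
#' @param phenotypes phenotype table with `sample_id`, `age`, `sex`.
#' @param pathways named list of gene sets (or the candidates frame
#'   from [select_candidates()] with its `genes` list-column).
#' @param fdr_alpha exploratory FDR cut-off (default 0.1).
#' @return data frame, one row per (pathway, gene): `pathway`, `gene`,
#'   `beta`, `se`, `t`, `pvalue`, `qvalue`, `significant`
#'   (q < `fdr_alpha`), `n`.
#' @export
pes_expression_scan <- function(scores, expression, phenotypes, pathways,
                                fdr_alpha = 0.1) {
  path_genes <- pathway_gene_list(pathways)
  samples <- Reduce(intersect, list(rownames(scores), colnames(expression),
                                    phenotypes$sample_id))
  if (length(samples) == 0L) stop_input("no samples shared across inputs")
  ph <- phenotypes[match(samples, phenotypes$sample_id), , drop = FALSE]
  sc <- scores[samples, , drop = FALSE]
  ex <- expression[, samples, drop = FALSE]
  out <- list()
  for (pw in names(path_genes)) {
    if (!pw %in% colnames(sc)) {
      warning("pes_expression_scan: no score column for pathway '", pw,
              "', skipped", call. = FALSE)
      next
    }
    genes <- intersect(path_genes[[pw]], rownames(ex))
    if (length(genes) == 0L) next
    x <- cbind(1, pes = sc[, pw], age = ph$age, sex = as.numeric(ph$sex),
               prs = sc[, "PRS_TOTAL"])
    if (stats::var(x[, "pes"]) == 0) {
      warning("pes_expression_scan: degenerate design (constant score) for '",
              pw, "', skipped", call. = FALSE)
      next
    }
    if (length(samples) <= ncol(x)) {
      warning("pes_expression_scan: n <= parameters for '", pw,
              "', skipped", call. = FALSE)
      next
    }
    qr_x <- qr(x)
    df_res <- length(samples) - qr_x$rank
    rows <- lapply(genes, function(g) {
      fit <- stats::lm.fit(x, ex[g, ])
      rss <- sum(fit$residuals^2)
      xtx_inv <- chol2inv(qr_x$qr[seq_len(qr_x$rank), seq_len(qr_x$rank),
                                  drop = FALSE])
      pos <- which(qr_x$pivot == 2L)
      beta <- unname(fit$coefficients[2])
      se <- sqrt(rss / df_res * xtx_inv[pos, pos])
      tval <- beta / se
      data.frame(pathway = pw, gene = g, beta = beta, se = se, t = tval,
                 pvalue = 2 * stats::pt(-abs(tval), df_res),
                 n = length(samples), stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, rows)
    block$qvalue <- bh_adjust(block$pvalue)
    block$significant <- block$qvalue < fdr_alpha
    out[[pw]] <- block
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    stop_input("pes_expression_scan: nothing testable")
  }
  rownames(res) <- NULL
  res[, c("pathway", "gene", "beta", "se", "t", "pvalue", "qvalue",
          "significant", "n")]
}

#' Count pathway genes with expression data
#'
#' Per pathway, the number of its genes present in the expression
#' matrix; the total sums over pathways, so a gene shared by two
#' pathways counts twice (matching the per-pathway testing structure).
#'
#' @param pathways named list of gene sets or candidates frame.
#' @param expression genes-by-individuals matrix (or character vector
#'   of measured gene ids).
#' @return list with `per_pathway` (named integer vector) and `total`.
#' @export
count_tested_genes <- function(pathways, expression) {
  path_genes <- pathway_gene_list(pathways)
  measured <- if (is.character(expression)) expression else rownames(expression)
  per <- vapply(path_genes, function(g) length(intersect(g, measured)),
                integer(1))
  list(per_pathway = per, total = sum(per))
}

# accept either a named list of gene_set objects or a candidates frame
pathway_gene_list <- function(pathways) {
  if (is.data.frame(pathways)) {
    stats::setNames(pathways$genes, pathways$set_name)
  } else {
    lapply(pathways, function(s) if (inherits(s, "gene_set")) s$genes else s)
  }
}
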