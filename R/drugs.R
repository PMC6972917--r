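#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} ( m * P_(j) / j )`, clipped at 1, returned in
#' the input order.
#'
#' @param pvalues numeric vector of P values in (0,1].
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(pvalues <= 0 | pvalues > 1)) {
    stop_input("bh_adjust: P values must lie in (0,1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Drug-target over-representation for one pathway
#'
#' For each drug, counts its target genes inside the pathway and tests
#' over-representation with the hypergeometric upper tail
#' `P(X >= k)` given universe size N, drug target count K (targets in
#' the universe) and pathway size n (pathway genes in the universe).
#' P values are BH-adjusted across all drugs tested for the pathway
#' (every drug with at least one target gene in the universe);
#' enriched drugs must satisfy both `q < fdr_alpha` and
#' `overlap >= min_overlap`.
#'
#' @param pathway a [gene_set()].
#' @param interactions drug-gene interaction data frame
#'   ([read_drug_interactions()]).
#' @param universe character vector of all annotated genes (must cover
#'   the pathway genes).
#' @param min_overlap minimum target overlap (default 3).
#' @param fdr_alpha FDR cut-off (default 0.05).
#' @param keep_all return all tested drugs, not only enriched ones.
#' @return data frame, one row per drug: `pathway`, `drug_name`,
#'   `overlap_k`, `universe_N`, `drug_targets_K`, `pathway_size_n`,
#'   `pvalue`, `fdr_q`, `atc_code`, `enriched`, plus list-column
#'   `overlap_genes`; sorted by q then decreasing overlap.
#' @export
drug_ora <- function(pathway, interactions, universe, min_overlap = 3,
                     fdr_alpha = 0.05, keep_all = FALSE) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop_input("drug_ora: empty universe")
  path_genes <- intersect(pathway$genes, universe)
  if (length(path_genes) < length(pathway$genes)) {
    stop_input("drug_ora: universe must contain all pathway genes")
  }
  n_univ <- length(universe)
  n_path <- length(path_genes)
  by_drug <- split(interactions, interactions$drug_name)
  rows <- lapply(names(by_drug), function(drug) {
    tg <- intersect(unique(by_drug[[drug]]$gene_id), universe)
    if (length(tg) == 0L) return(NULL)
    ov <- intersect(tg, path_genes)
    k <- length(ov)
    p <- stats::phyper(k - 1, length(tg), n_univ - length(tg), n_path,
                       lower.tail = FALSE)
    atc <- by_drug[[drug]]$atc_code[1]
    data.frame(pathway = pathway$name, drug_name = drug, overlap_k = k,
               universe_N = n_univ, drug_targets_K = length(tg),
               pathway_size_n = n_path, pvalue = p,
               atc_code = atc, overlap_genes = I(list(ov)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(pathway = character(0), drug_name = character(0),
                      overlap_k = integer(0), pvalue = numeric(0),
                      fdr_q = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  # a tail probability of exactly 0 cannot arise from phyper, but guard
  # the q computation against underflow to keep q finite
  res$pvalue <- pmax(res$pvalue, .Machine$double.xmin)
  res$fdr_q <- bh_adjust(res$pvalue)
  res$enriched <- res$fdr_q < fdr_alpha & res$overlap_k >= min_overlap
  res <- res[order(res$fdr_q, -res$overlap_k, res$drug_name), , drop = FALSE]
  rownames(res) <- NULL
  if (keep_all) res else res[res$enriched, , drop = FALSE]
}

#' Select the top drug for a pathway
#'
#' Two modes.  `interaction_score`: among approved drugs interacting
#' with a druggable (T_Clin) gene of the pathway, pick the pair with
#' the highest interaction-confidence score.  `ora`: run the
#' over-representation analysis and pick the drug with the smallest
#' q-value; when q-values tie, the drug with the larger gene-set
#' overlap wins, remaining ties resolved by lexicographic drug name.
#'
#' @param pathway a [gene_set()] with `druggable_genes` populated.
#' @param interactions drug-gene interaction data frame.
#' @param mode `"interaction_score"` or `"ora"`.
#' @param universe gene universe (required for `ora` mode).
#' @param ... further arguments for [drug_ora()].
#' @return one-row data frame describing the selected drug, or a
#'   zero-row frame (with a warning) when no eligible drug exists.
#' @export
select_top_drug <- function(pathway, interactions,
                            mode = c("interaction_score", "ora"),
                            universe = NULL, ...) {
  mode <- match.arg(mode)
  if (mode == "interaction_score") {
    cand <- interactions[interactions$approved &
                           interactions$gene_id %in% pathway$druggable_genes,
                         , drop = FALSE]
    if (nrow(cand) == 0L) {
      warning("select_top_drug: no approved interaction for pathway '",
              pathway$name, "'", call. = FALSE)
      return(cand)
    }
    cand <- cand[order(-cand$interaction_score, cand$drug_name), , drop = FALSE]
    out <- cand[1, , drop = FALSE]
    out$pathway <- pathway$name
    rownames(out) <- NULL
    return(out)
  }
  if (is.null(universe)) stop_input("ora mode requires a universe")
  res <- drug_ora(pathway, interactions, universe, ...)
  if (nrow(res) == 0L) {
    warning("select_top_drug: no enriched drug for pathway '",
            pathway$name, "'", call. = FALSE)
    return(res)
  }
  # drug_ora already orders by (q, -overlap, name)
  res[1, , drop = FALSE]
}
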