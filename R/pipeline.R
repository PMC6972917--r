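#' Run the PES pipeline end to end
#'
#' Convenience driver over the module functions: gene-level analysis at
#' the threshold grid, competitive association of druggable sets,
#' candidate selection, PES score definitions, genome-wide PRS
#' optimisation, the individual score matrix, and percentile flags.
#'
#' @param sumstats GWAS summary statistics.
#' @param annotation gene annotation table.
#' @param sets gene-set collection (named list).
#' @param druggable_genes druggable-gene list.
#' @param gm target-cohort `genotype_matrix` (also the LD reference).
#' @param phenotypes phenotype/covariate table.
#' @param thresholds gene-analysis threshold grid.
#' @param alpha candidate-selection threshold (default 0.001).
#' @param clump_r2,clump_kb clumping parameters.
#' @param percentile_levels elevated-score levels.
#' @return list with `gene_results`, `set_results`, `candidates`,
#'   `definitions`, `prs` (optimisation result), `scores`, `flags`.
#' @export
run_pes_pipeline <- function(sumstats, annotation, sets, druggable_genes,
                             gm, phenotypes,
                             thresholds = threshold_config(),
                             alpha = 0.001, clump_r2 = 0.1, clump_kb = 250,
                             percentile_levels = c(0.75, 0.90, 0.99)) {
  druggable <- flag_druggable(sets, druggable_genes)
  gene_results <- run_gene_analysis(sumstats, annotation, gm,
                                    thresholds = thresholds)
  set_results <- run_set_analysis(gene_results, druggable$retained)
  candidates <- select_candidates(set_results, sets = sets, alpha = alpha)
  gmap <- map_snps_to_genes(sumstats, annotation)
  out <- list(gene_results = gene_results, set_results = set_results,
              candidates = candidates)
  if (nrow(candidates) == 0L) return(out)
  defs <- build_pes_definitions(candidates, sumstats, gmap, gm,
                                clump_r2 = clump_r2, clump_kb = clump_kb)
  prs <- optimise_total_prs(sumstats, gm, phenotypes,
                            clump_r2 = clump_r2, clump_kb = clump_kb)
  scores <- score_matrix(defs, gm, total_definition = prs$definition)
  flags <- flag_percentiles(scores[, names(defs), drop = FALSE],
                            levels = percentile_levels)
  c(out, list(definitions = defs, prs = prs, scores = scores,
              flags = flags))
}
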