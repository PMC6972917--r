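#' Greedy LD clumping
#'
#' PRS-style clumping: iterate variants by ascending GWAS P value
#' (ties broken by lexicographic SNP id for determinism); retain each
#' index SNP and remove not-yet-retained SNPs on the same chromosome
#' within `window_kb` whose squared correlation with it exceeds `r2`.
#' SNPs absent from the LD reference are treated as unlinked and
#' logged.
#'
#' @param sumstats summary-statistics data frame.
#' @param ld_reference reference `genotype_matrix`.
#' @param r2 squared-correlation threshold (default 0.1).
#' @param window_kb clumping window in kb (default 250).
#' @param p_max only variants with `pvalue <= p_max` are considered.
#' @return character vector of retained SNP ids.
#' @export
ld_clump <- function(sumstats, ld_reference, r2 = 0.1, window_kb = 250,
                     p_max = 1.0) {
  if (r2 <= 0 || window_kb <= 0) stop_input("clump parameters must be positive")
  ss <- sumstats[sumstats$pvalue <= p_max, , drop = FALSE]
  if (nrow(ss) == 0L) return(character(0))
  ord <- order(ss$pvalue, ss$snp_id)
  ss <- ss[ord, , drop = FALSE]
  ref_idx <- match(ss$snp_id, ld_reference$variants$snp_id)
  n_missing <- sum(is.na(ref_idx))
  if (n_missing > 0) {
    pes_log("ld_clump: %d SNP(s) absent from reference, treated as unlinked",
            n_missing)
  }
  dos <- mean_impute_dosages(ld_reference)$dosages
  window <- window_kb * 1000
  n <- nrow(ss)
  alive <- rep(TRUE, n)
  retained <- logical(n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    retained[i] <- TRUE
    alive[i] <- FALSE
    if (is.na(ref_idx[i])) next
    cand <- which(alive & ss$chrom == ss$chrom[i] &
                    abs(ss$pos - ss$pos[i]) <= window & !is.na(ref_idx))
    if (length(cand) == 0L) next
    r <- suppressWarnings(
      stats::cor(dos[, ref_idx[i]], dos[, ref_idx[cand], drop = FALSE])
    )
    r[is.na(r)] <- 0
    alive[cand[r^2 > r2]] <- FALSE
  }
  ss$snp_id[retained]
}

#' Score definition
#'
#' Bundles the aligned SNP weights of one score: a pathway-restricted
#' PES or the genome-wide `TOTAL` score.
#'
#' @param name score name.
#' @param snp_id character vector of SNP ids (as named in the genotype
#'   matrix).
#' @param beta effect sizes aligned to the counted allele.
#' @param p_threshold the P ceiling the score was built at.
#' @param pathway source pathway name, or `"TOTAL"`.
#' @export
score_definition <- function(name, snp_id, beta, p_threshold = 1,
                             pathway = "TOTAL") {
  if (length(snp_id) == 0L) stop_input("score '", name, "' has no SNPs")
  if (length(beta) != length(snp_id) || any(!is.finite(beta))) {
    stop_input("score '", name, "' has invalid effect sizes")
  }
  structure(list(name = name, snp_id = as.character(snp_id),
                 beta = as.numeric(beta), p_threshold = p_threshold,
                 pathway = pathway),
            class = "score_definition")
}

#' Compute an additive polygenic score
#'
#' For individual i the score is the plain sum over the definition's
#' SNPs of the GWAS effect size times the dosage of the counted allele:
#' `score_i = sum_j beta_j * G_ij`.  Missing dosages are mean-imputed
#' per variant; definition SNPs absent from the genotype matrix are
#' dropped with a log entry.  Set `average = TRUE` to divide by the
#' number of SNPs used (off by default: the raw sum is the score).
#'
#' @param defn a [score_definition()].
#' @param gm a `genotype_matrix`.
#' @param average divide by SNP count (default FALSE).
#' @return named numeric vector of scores (one per individual) with
#'   attribute `n_snps_used`.
#' @export
compute_score <- function(defn, gm, average = FALSE) {
  j <- match(defn$snp_id, gm$variants$snp_id)
  present <- !is.na(j)
  if (!any(present)) {
    stop_input("compute_score: no SNPs of score '", defn$name,
               "' present in the genotype matrix")
  }
  if (any(!present)) {
    pes_log("compute_score[%s]: dropped %d SNP(s) absent from genotypes",
            defn$name, sum(!present))
  }
  d <- mean_impute_dosages(gm)$dosages[, j[present], drop = FALSE]
  s <- as.vector(d %*% defn$beta[present])
  if (average) s <- s / sum(present)
  names(s) <- gm$samples
  attr(s, "n_snps_used") <- sum(present)
  s
}

#' Build PES score definitions for candidate pathways
#'
#' For each candidate pathway: collect the SNPs mapped to the pathway's
#' genes, keep those strictly below the pathway's selected P threshold,
#' clump them against the reference, and harmonise effect alleles with
#' the target genotype matrix.  Pathways left with no SNP after
#' thresholding and clumping are skipped with a warning.
#'
#' @param candidates data frame from [select_candidates()] (requires
#'   the `genes` list-column).
#' @param sumstats summary-statistics data frame.
#' @param gene_map a `gene_snp_map` from [map_snps_to_genes()].
#' @param gm target `genotype_matrix` (also the clumping reference
#'   unless `ld_reference` is given).
#' @param ld_reference optional separate LD reference panel.
#' @param clump_r2,clump_kb clumping parameters.
#' @return list of [score_definition()]s, one per retained pathway.
#' @export
build_pes_definitions <- function(candidates, sumstats, gene_map, gm,
                                  ld_reference = NULL,
                                  clump_r2 = 0.1, clump_kb = 250) {
  ld_reference <- ld_reference %||% gm
  harmonised <- harmonise_alleles(sumstats, gm)
  defs <- list()
  for (i in seq_len(nrow(candidates))) {
    genes <- candidates$genes[[i]]
    snps <- unique(unlist(gene_map[intersect(genes, names(gene_map))],
                          use.names = FALSE))
    ss <- sumstats[sumstats$snp_id %in% snps, , drop = FALSE]
    ss <- subset_by_threshold(ss, candidates$p_threshold[i])
    if (nrow(ss) > 0L) {
      kept <- ld_clump(ss, ld_reference, r2 = clump_r2, window_kb = clump_kb)
      h <- harmonised[harmonised$snp_id %in% kept, , drop = FALSE]
    } else {
      h <- harmonised[0, , drop = FALSE]
    }
    if (nrow(h) == 0L) {
      warning("build_pes_definitions: pathway '", candidates$set_name[i],
              "' has no scoreable SNPs and was skipped", call. = FALSE)
      next
    }
    defs[[candidates$set_name[i]]] <- score_definition(
      name = candidates$set_name[i], snp_id = h$snp_id, beta = h$beta,
      p_threshold = candidates$p_threshold[i],
      pathway = candidates$set_name[i]
    )
  }
  defs
}

#' Nagelkerke pseudo R-squared
#'
#' `R2 = [1 - exp((2/n)(L0 - L1))] / [1 - exp((2/n) L0)]`, the
#' Cox-Snell ratio rescaled to attain 1 at a perfect fit, computed from
#' the null and full model log-likelihoods.
#'
#' @param loglik_null log-likelihood of the null model.
#' @param loglik_full log-likelihood of the full model (>= null).
#' @param n number of observations.
#' @export
nagelkerke_r2 <- function(loglik_null, loglik_full, n) {
  if (n < 1) stop_input("n must be >= 1")
  if (loglik_full < loglik_null - 1e-8) {
    stop_input("loglik_full must be >= loglik_null")
  }
  denom <- 1 - exp((2 / n) * loglik_null)
  if (denom == 0) stop_input("saturated null model: Nagelkerke R2 undefined")
  r2 <- (1 - exp((2 / n) * (loglik_null - loglik_full))) / denom
  min(max(r2, 0), 1)
}

#' Optimise the genome-wide PRS threshold by Nagelkerke R-squared
#'
#' Clumps the full summary statistics once (at `p_max = 1`), then for
#' each P ceiling of the grid computes the genome-wide score over SNPs
#' strictly below the ceiling and its incremental Nagelkerke R-squared:
#' the R-squared of `case ~ score + covariates` minus that of the
#' covariates-only model (both against the intercept-only null).  The
#' ceiling explaining the most case-control variance is chosen; exact
#' ties go to the smaller ceiling.
#'
#' @param sumstats summary-statistics data frame.
#' @param gm target `genotype_matrix`.
#' @param phenotypes phenotype table (`sample_id`, `case_status`,
#'   covariate columns).
#' @param grid P ceilings to scan.
#' @param covariates covariate column names (default sex + PC1..PC3
#'   where present).
#' @param clump_r2,clump_kb clumping parameters.
#' @param ld_reference optional separate LD reference panel.
#' @return list with `grid` (data frame: p_t, r2, n_snps), `chosen_p_t`,
#'   `r2`, and `definition` (the chosen [score_definition()]).
#' @export
optimise_total_prs <- function(sumstats, gm, phenotypes,
                               grid = c(5e-8, 1e-5, 1e-3, 0.01, 0.05,
                                        0.1, 0.2, 0.5, 1.0),
                               covariates = NULL,
                               clump_r2 = 0.1, clump_kb = 250,
                               ld_reference = NULL) {
  if (length(grid) == 0L) stop_input("empty threshold grid")
  if (length(unique(phenotypes$case_status)) < 2L) {
    stop_input("phenotype has a single class; cannot optimise")
  }
  ld_reference <- ld_reference %||% gm
  kept <- ld_clump(sumstats, ld_reference, r2 = clump_r2,
                   window_kb = clump_kb, p_max = 1.0)
  ss <- sumstats[sumstats$snp_id %in% kept, , drop = FALSE]
  h <- harmonise_alleles(ss, gm)
  covariates <- covariates %||%
    intersect(c("sex", "PC1", "PC2", "PC3"), names(phenotypes))
  i <- match(gm$samples, phenotypes$sample_id)
  ph <- phenotypes[i, , drop = FALSE]
  y <- ph$case_status
  covar_mat <- if (length(covariates)) {
    as.matrix(ph[, covariates, drop = FALSE])
  } else NULL
  n <- length(y)
  ll0 <- loglik_binomial_null(y)
  ll_cov <- loglik_logistic(y, covar_mat)
  r2_cov <- nagelkerke_r2(ll0, ll_cov, n)
  grid <- sort(grid)
  rows <- lapply(grid, function(p_t) {
    hh <- if (p_t == 1) h else h[h$pvalue < p_t, , drop = FALSE]
    if (nrow(hh) == 0L) {
      return(data.frame(p_t = p_t, r2 = 0, n_snps = 0L))
    }
    defn <- score_definition(sprintf("PRS_pt_%g", p_t), hh$snp_id, hh$beta,
                             p_threshold = p_t)
    s <- compute_score(defn, gm)
    ll_full <- loglik_logistic(y, cbind(covar_mat, score = s))
    r2 <- nagelkerke_r2(ll0, ll_full, n) - r2_cov
    data.frame(p_t = p_t, r2 = r2, n_snps = nrow(hh))
  })
  tab <- do.call(rbind, rows)
  best <- which(tab$r2 == max(tab$r2))[1]  # grid sorted: ties -> smaller p_t
  p_best <- tab$p_t[best]
  hh <- if (p_best == 1) h else h[h$pvalue < p_best, , drop = FALSE]
  defn <- score_definition("PRS_TOTAL", hh$snp_id, hh$beta,
                           p_threshold = p_best)
  list(grid = tab, chosen_p_t = p_best, r2 = tab$r2[best], definition = defn)
}

# log-likelihood of a logistic fit of y on an intercept plus X (may be NULL)
loglik_logistic <- function(y, x = NULL) {
  if (is.null(x)) return(loglik_binomial_null(y))
  fit <- stats::glm.fit(cbind(1, x), y, family = stats::binomial())
  p <- fit$fitted.values
  sum(y * log(p) + (1 - y) * log1p(-p))
}

loglik_binomial_null <- function(y) {
  p <- mean(y)
  if (p == 0 || p == 1) return(0)
  sum(y * log(p) + (1 - y) * log1p(-p))
}

#' Assemble the individual-by-score matrix
#'
#' Computes every PES plus the genome-wide total score over one
#' genotype matrix, in a deterministic column order (pathways in the
#' order given, `PRS_TOTAL` last).
#'
#' @param definitions list of [score_definition()]s.
#' @param gm a `genotype_matrix`.
#' @param total_definition optional `PRS_TOTAL` [score_definition()].
#' @return numeric matrix, individuals by scores, with attribute
#'   `n_snps` (per-column SNP counts used).
#' @export
score_matrix <- function(definitions, gm, total_definition = NULL) {
  all_defs <- definitions
  if (!is.null(total_definition)) all_defs <- c(all_defs, list(PRS_TOTAL = total_definition))
  cols <- lapply(all_defs, compute_score, gm = gm)
  m <- do.call(cbind, cols)
  colnames(m) <- names(all_defs) %||%
    vapply(all_defs, `[[`, character(1), "name")
  rownames(m) <- gm$samples
  attr(m, "n_snps") <- vapply(cols, attr, numeric(1), "n_snps_used")
  m
}
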