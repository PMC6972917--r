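#' Flag individuals with elevated scores at percentile cut-offs
#'
#' For each score column and each level q, flags the top
#' `ceil((1-q) * N)` individuals under the nearest-rank rule; ties at
#' the boundary value are all flagged.  Percentiles are computed over
#' whichever cohort the score matrix covers (by default the pooled
#' case-control study population); pass `subset` to rank within a
#' sub-cohort instead.
#'
#' @param scores numeric matrix, individuals by score columns.
#' @param levels percentile levels (default 0.75, 0.90, 0.99).
#' @param subset optional character vector of sample ids defining the
#'   ranking population (rows outside it are neither ranked nor
#'   flagged).
#' @return object of class `percentile_flags`: list with `flags` (a
#'   named list of logical matrices, one per level) and `counts` (an
#'   individuals-by-levels integer matrix of per-individual elevated
#'   score counts, columns `n75`, `n90`, `n99`-style).
#' @export
flag_percentiles <- function(scores, levels = c(0.75, 0.90, 0.99),
                             subset = NULL) {
  scores <- as.matrix(scores)
  if (!is.null(subset)) {
    scores <- scores[rownames(scores) %in% subset, , drop = FALSE]
  }
  n <- nrow(scores)
  if (n < 2L) stop_input("flag_percentiles: need >= 2 individuals")
  levels <- sort(levels)
  flags <- lapply(levels, function(q) {
    k <- ceiling(round((1 - q) * n, 9))
    f <- apply(scores, 2, function(col) {
      if (max(col) == min(col)) {
        warning("flag_percentiles: constant score column", call. = FALSE)
        return(rep(TRUE, n))
      }
      cut <- sort(col, decreasing = TRUE)[k]
      col >= cut
    })
    rownames(f) <- rownames(scores)
    f
  })
  names(flags) <- sprintf("p%g", 100 * levels)
  counts <- vapply(flags, rowSums, numeric(n))
  counts <- matrix(as.integer(counts), nrow = n,
                   dimnames = list(rownames(scores),
                                   sprintf("n%g", 100 * levels)))
  structure(list(flags = flags, counts = counts, levels = levels),
            class = "percentile_flags")
}

#' Logistic case-control association with Wald inference
#'
#' Binomial logistic regression of case status on a score (or an
#' elevated-score count), adjusted for sex and the leading principal
#' components, optionally also for the genome-wide `PRS_TOTAL`.
#' Reports the Wald z (`beta/se`), two-sided P, odds ratio and 95%
#' confidence interval `exp(beta +/- 1.96 se)` for the predictor term.
#'
#' @param predictor named numeric vector (names = sample ids) or
#'   unnamed vector aligned with `phenotypes` rows.
#' @param phenotypes phenotype table with `sample_id`, `case_status`
#'   and the covariate columns.
#' @param covariates covariate column names (default sex + PC1..PC3
#'   where present).
#' @param prs optional named `PRS_TOTAL` vector; included as a
#'   covariate when `adjust_prs = TRUE`.
#' @param adjust_prs adjust for the genome-wide score (default FALSE).
#' @return one-row data frame: `term`, `beta`, `se`, `z`, `wald_p`,
#'   `odds_ratio`, `ci95_low`, `ci95_high`, `prs_adjusted`, `n`.
#' @export
associate_with_case <- function(predictor, phenotypes, covariates = NULL,
                                prs = NULL, adjust_prs = FALSE) {
  covariates <- covariates %||%
    intersect(c("sex", "PC1", "PC2", "PC3"), names(phenotypes))
  if (!is.null(names(predictor))) {
    i <- match(names(predictor), phenotypes$sample_id)
    if (anyNA(i)) stop_input("predictor has sample ids absent from phenotypes")
    ph <- phenotypes[i, , drop = FALSE]
  } else {
    if (length(predictor) != nrow(phenotypes)) {
      stop_input("unnamed predictor must align with phenotype rows")
    }
    ph <- phenotypes
  }
  if (length(unique(ph$case_status)) < 2L) {
    stop_input("both case and control classes required")
  }
  if (stats::var(predictor) == 0) {
    stop_input("degenerate design: predictor is constant")
  }
  df <- data.frame(y = ph$case_status, x = as.numeric(predictor))
  for (cv in covariates) df[[cv]] <- ph[[cv]]
  if (adjust_prs) {
    if (is.null(prs)) stop_input("adjust_prs = TRUE requires a prs vector")
    df$PRS_TOTAL <- as.numeric(prs[match(ph$sample_id, names(prs))])
  }
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
  if (!fit$converged) {
    stop_input("logistic fit did not converge (possible separation)")
  }
  sm <- summary(fit)$coefficients
  beta <- sm["x", 1]; se <- sm["x", 2]
  if (se > 100) {
    stop_input("logistic fit unstable (SE > 100; possible separation)")
  }
  z <- beta / se
  data.frame(term = "x", beta = beta, se = se, z = z,
             wald_p = max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin),
             odds_ratio = exp(beta),
             ci95_low = exp(beta - 1.96 * se),
             ci95_high = exp(beta + 1.96 * se),
             prs_adjusted = adjust_prs, n = nrow(df),
             stringsAsFactors = FALSE)
}

#' Cluster-enrichment test for elevated-score carriers
#'
#' Multinomial logistic regression of mixture-cluster membership on a
#' carrier flag (e.g. "has at least one top-percentile PES") plus sex
#' and principal components.  The largest cluster is the reference;
#' for every other cluster the carrier coefficient is divided by its
#' standard error to give a Wald z and two-sided P.  Clusters with
#' fewer than `min_size` members are dropped from the test.
#'
#' @param assignments integer cluster assignments (one per individual,
#'   aligned with `phenotypes` rows or named by sample id).
#' @param carrier_flag logical/0-1 vector, same alignment.
#' @param phenotypes phenotype table.
#' @param covariates covariate column names (default sex + PC1..PC3).
#' @param min_size minimum cluster size kept (default 5).
#' @return data frame with one row per non-reference cluster: `cluster`,
#'   `reference`, `beta`, `se`, `z`, `wald_p`, `n`.
#' @export
cluster_enrichment <- function(assignments, carrier_flag, phenotypes,
                               covariates = NULL, min_size = 5L) {
  covariates <- covariates %||%
    intersect(c("sex", "PC1", "PC2", "PC3"), names(phenotypes))
  cl <- as.integer(assignments)
  sizes <- table(cl)
  keep_cl <- as.integer(names(sizes)[sizes >= min_size])
  if (length(keep_cl) < length(sizes)) {
    pes_log("cluster_enrichment: dropped %d cluster(s) with < %d members",
            length(sizes) - length(keep_cl), min_size)
  }
  if (length(keep_cl) < 2L) stop_input("need >= 2 clusters of sufficient size")
  keep <- cl %in% keep_cl
  cl <- cl[keep]
  ref <- as.integer(names(which.max(sizes[as.character(keep_cl)])))
  df <- data.frame(cluster = stats::relevel(factor(cl), ref = as.character(ref)),
                   carrier = as.numeric(carrier_flag[keep]))
  for (cv in covariates) df[[cv]] <- phenotypes[[cv]][keep]
  fit <- nnet::multinom(cluster ~ ., data = df, trace = FALSE, maxit = 500)
  co <- coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (is.null(dim(co))) {
    # two clusters: nnet returns a vector
    co <- matrix(co, nrow = 1,
                 dimnames = list(setdiff(levels(df$cluster),
                                         as.character(ref)), names(co)))
  }
  rows <- lapply(rownames(co), function(lev) {
    b <- co[lev, "carrier"]
    s <- if (nlevels(df$cluster) == 2L) se["carrier"] else
      se[paste0(lev, ":carrier")]
    z <- b / s
    data.frame(cluster = as.integer(lev), reference = ref,
               beta = b, se = unname(s), z = unname(z),
               wald_p = max(2 * stats::pnorm(-abs(unname(z))),
                            .Machine$double.xmin),
               n = sum(cl == as.integer(lev)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
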