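#' Map SNPs to genes with regulatory windows
#'
#' Assigns each summary-statistic SNP to every gene whose window
#' contains it.  Windows extend `window_up` bp upstream of the
#' transcription start and `window_down` bp downstream of the gene end
#' on the strand-adjusted axis: a + strand gene spans
#' `[start - window_up, end + window_down]`, a - strand gene
#' `[start - window_down, end + window_up]`; unknown strand is treated
#' as +.  The asymmetric default (5 kb up, 1.5 kb down) captures the
#' more extensive regulatory elements before the transcription start
#' site.  Genes overlapping the MHC interval on chromosome 6 are
#' excluded by default because of the region's haplotype complexity.
#'
#' @param sumstats summary-statistics data frame.
#' @param annotation gene annotation from [read_gene_annotation()].
#' @param window_up upstream window in bp (default 5000).
#' @param window_down downstream window in bp (default 1500).
#' @param exclude_mhc drop genes in the MHC interval (default TRUE).
#' @param mhc_interval list(chrom, start, end); default chr6:25-34 Mb
#'   (GRCh37).
#' @return object of class `gene_snp_map`: named list mapping gene_id
#'   to the character vector of its SNP ids (position order), with the
#'   window parameters as attributes.
#' @export
map_snps_to_genes <- function(sumstats, annotation, window_up = 5000,
                              window_down = 1500, exclude_mhc = TRUE,
                              mhc_interval = list(chrom = "6",
                                                  start = 25e6, end = 34e6)) {
  ann <- annotation
  if (exclude_mhc) {
    in_mhc <- ann$chrom == mhc_interval$chrom &
      ann$end >= mhc_interval$start & ann$start <= mhc_interval$end
    ann <- ann[!in_mhc, , drop = FALSE]
  }
  ss <- sumstats[order(sumstats$chrom, sumstats$pos), , drop = FALSE]
  map <- vector("list", nrow(ann))
  names(map) <- ann$gene_id
  for (g in seq_len(nrow(ann))) {
    up <- if (ann$strand[g] == "-") window_down else window_up
    dn <- if (ann$strand[g] == "-") window_up else window_down
    lo <- ann$start[g] - up
    hi <- ann$end[g] + dn
    hit <- ss$chrom == ann$chrom[g] & ss$pos >= lo & ss$pos <= hi
    map[[g]] <- ss$snp_id[hit]
  }
  map <- map[vapply(map, length, integer(1)) > 0L]
  if (length(map) == 0L) {
    warning("map_snps_to_genes: no SNP maps to any gene", call. = FALSE)
  }
  structure(map, class = "gene_snp_map", window_up = window_up,
            window_down = window_down, mhc_excluded = exclude_mhc)
}

#' Pairwise LD matrix from reference dosages
#'
#' Pearson correlation of (mean-imputed) dosages for the requested
#' SNPs.  Monomorphic variants get zero off-diagonal correlation and a
#' unit diagonal.  The matrix is shrunk toward the identity
#' (`(1-lambda) R + lambda I`) when its smallest eigenvalue falls below
#' `psd_tol`, keeping the null-variance computation well behaved.
#'
#' @param gm reference `genotype_matrix`.
#' @param snp_ids SNPs to include (must be present in `gm`).
#' @param lambda shrinkage weight applied on regularisation.
#' @param psd_tol eigenvalue tolerance triggering regularisation.
#' @return correlation matrix with `snp_ids` dimnames.
#' @export
ld_matrix <- function(gm, snp_ids, lambda = 0.001, psd_tol = 1e-8) {
  j <- match(snp_ids, gm$variants$snp_id)
  if (anyNA(j)) {
    stop_input("SNP(s) absent from reference: ",
               paste(utils::head(snp_ids[is.na(j)], 5), collapse = ", "))
  }
  d <- mean_impute_dosages(gm)$dosages[, j, drop = FALSE]
  ld_from_dosages(d, snp_ids, lambda, psd_tol)
}

# correlation matrix of (already imputed) dosage columns with the same
# regularisation policy as ld_matrix
ld_from_dosages <- function(d, snp_ids, lambda = 0.001, psd_tol = 1e-8) {
  R <- suppressWarnings(stats::cor(d))
  R[is.na(R)] <- 0
  diag(R) <- 1
  if (nrow(R) > 1) {
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < psd_tol) {
      warning("ld_matrix: regularising non-PSD correlation matrix",
              call. = FALSE)
      R <- (1 - lambda) * R + lambda * diag(nrow(R))
    }
  }
  dimnames(R) <- list(snp_ids, snp_ids)
  R
}

#' Gene-level omnibus P value under LD
#'
#' Combines the variant-wise P values of one gene into a single gene
#' P value while accounting for linkage disequilibrium.  Each P value
#' is converted to a two-sided chi-square(1) deviate
#' `q_j = probit(1 - P_j/2)^2` and the statistic is the linear
#' combination `T = sum_j q_j`.  Under the null, `T = z'z` with
#' `z ~ MVN(0, R)` for LD matrix R — a weighted sum of chi-square(1)
#' variables weighted by the eigenvalues of R — and the gene P value
#' is this distribution's upper tail at T, evaluated exactly by
#' numerical characteristic-function inversion (Imhof's method).
#' Brown/Satterthwaite moment matching (`E[T] = M`,
#' `Var[T] = 2M + 4 * sum_{j<k} r_jk^2`, scale `c = Var/(2E)`,
#' `nu = 2E^2/Var` degrees of freedom) is reported alongside as a
#' summary of the null's spread and serves as the fallback tail if the
#' quadrature fails.  The probit of `1 - P` gives the gene Z score,
#' clamped to +/- `z_clamp` to guard probit overflow.
#'
#' Perfectly correlated variants (|r| = 1, e.g. a duplicated SNP) carry
#' no independent information; each such group is collapsed to a single
#' effective SNP (its mean chi-square transform) before the moment
#' matching, which makes the gene P value exactly invariant to
#' duplicating any SNP.  With a single SNP the construction reproduces
#' the SNP P value exactly.
#'
#' @param pvalues numeric vector of variant P values in (0,1].
#' @param ld LD correlation matrix covering exactly these SNPs (may be
#'   omitted for a single SNP; identity assumed if NULL).
#' @param gene_id optional label carried into the result.
#' @param p_threshold optional P_T label carried into the result.
#' @param z_clamp probit clamp for the gene Z (default 8.2).
#' @return one-row data frame: `gene_id`, `p_threshold`, `n_snps`,
#'   `statistic`, `scale`, `df`, `gene_p`, `gene_z`.
#' @export
gene_omnibus_test <- function(pvalues, ld = NULL, gene_id = NA_character_,
                              p_threshold = NA_real_, z_clamp = 8.2) {
  m <- length(pvalues)
  if (m == 0L) stop_input("gene_omnibus_test: no P values")
  if (any(pvalues <= 0 | pvalues > 1)) {
    stop_input("gene_omnibus_test: P values must lie in (0,1]")
  }
  if (is.null(ld)) ld <- diag(m)
  if (!all(dim(ld) == c(m, m))) {
    stop_input("LD matrix dimensions do not match the SNP set")
  }
  # upper-tail form avoids cancellation in 1 - P/2 at very small P
  q <- stats::qnorm(pvalues / 2, lower.tail = FALSE)^2
  # Perfectly correlated variants (|r| = 1) are statistically identical
  # copies; collapse each such group to one effective SNP (mean q) so a
  # duplicated variant can never change the gene P value.
  if (m > 1) {
    grp <- perfect_ld_groups(ld)
    if (length(grp) < m) {
      q <- vapply(grp, function(idx) mean(q[idx]), numeric(1))
      reps <- vapply(grp, `[[`, integer(1), 1L)
      ld <- ld[reps, reps, drop = FALSE]
      m_eff <- length(grp)
    } else {
      m_eff <- m
    }
  } else {
    m_eff <- 1L
  }
  stat <- sum(q)
  e_t <- m_eff
  off <- ld[upper.tri(ld)]
  var_t <- 2 * m_eff + 4 * sum(off^2)
  scale <- var_t / (2 * e_t)
  df <- 2 * e_t^2 / var_t
  # Null law of the statistic: T = z' z with z ~ MVN(0, R), i.e. a
  # weighted sum of chi-square(1) variables with weights the
  # eigenvalues of R.  The tail is evaluated exactly by numerical
  # characteristic-function inversion; the moment-matched scaled
  # chi-square (scale, df above) is reported alongside and used as a
  # fallback if the quadrature fails.
  if (m_eff == 1L) {
    # exact inverse of the probit transform: avoids the precision loss
    # of the chi-square tail round-trip at very small P
    gene_p <- 2 * stats::pnorm(-sqrt(stat))
    lam <- 1
  } else {
    lam <- eigen(ld, symmetric = TRUE, only.values = TRUE)$values
    lam <- lam[lam > 1e-10]
    gene_p <- wchisq_tail(stat, lam)
  }
  if (!is.finite(gene_p)) {
    gene_p <- stats::pchisq(stat / scale, df = df, lower.tail = FALSE)
  }
  # keep gene_p inside (0,1) so the probit is finite
  gene_p <- min(max(gene_p, .Machine$double.xmin), 1 - 1e-16)
  gene_z <- max(min(stats::qnorm(1 - gene_p), z_clamp), -z_clamp)
  data.frame(gene_id = gene_id, p_threshold = p_threshold, n_snps = m,
             statistic = stat, scale = scale, df = df,
             gene_p = gene_p, gene_z = gene_z, stringsAsFactors = FALSE)
}

# Upper tail P(sum_i lambda_i w_i > t), w_i ~ iid chi-square(1), by
# Imhof's characteristic-function inversion.  Exact up to quadrature
# tolerance; reduces to pchisq when all weights are equal.
wchisq_tail <- function(t, lambda) {
  m <- length(lambda)
  if (m == 0L) return(NA_real_)
  if (max(lambda) - min(lambda) < 1e-12) {
    return(stats::pchisq(t / lambda[1], df = m, lower.tail = FALSE))
  }
  if (m == 2L) return(wchisq_tail2(t, lambda))
  imhof_integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * t * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  # fixed-grid midpoint evaluation: the integrand magnitude is bounded
  # by u^(-1 - m/2) / prod(sqrt(lambda)), giving an explicit truncation
  # point; the grid step resolves the sin(theta) oscillation, whose
  # frequency is at most (t + sum(lambda)) / 2
  val <- NA_real_
  cut <- ((2 / m) / (prod(sqrt(lambda)) * pi * 1e-6))^(2 / m)
  step <- (2 * pi / (0.5 * (t + sum(lambda)))) / 24
  n_pts <- ceiling(cut / step)
  if (n_pts <= 2e6) {
    val <- 0
    for (lo in seq(0L, n_pts - 1L, by = 250000L)) {
      k <- (lo + 1L):min(lo + 250000L, n_pts)
      val <- val + step * sum(imhof_integrand(step * (k - 0.5)))
    }
  }
  if (!is.finite(val)) {
    for (tol in c(1e-8, 1e-6, 1e-4)) {
      val <- tryCatch(
        stats::integrate(imhof_integrand, 0, Inf, rel.tol = tol,
                         subdivisions = 1000L)$value,
        error = function(e) NA_real_
      )
      if (is.finite(val)) break
    }
  }
  if (!is.finite(val)) return(NA_real_)
  min(max(0.5 + val / pi, 0), 1)
}

# two weights: smooth conditional-expectation form
# P(l1 W1 + l2 W2 > t) = E_Z[ Q_chisq1( (t - l2 Z^2) / l1 ) ], Z ~ N(0,1)
wchisq_tail2 <- function(t, lambda) {
  l1 <- max(lambda); l2 <- min(lambda)
  f <- function(z) {
    rem <- (t - l2 * z^2) / l1
    out <- numeric(length(z))
    pos <- rem > 0
    out[pos] <- stats::pchisq(rem[pos], df = 1, lower.tail = FALSE)
    out[!pos] <- 1
    2 * stats::dnorm(z) * out
  }
  val <- tryCatch(
    stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value,
    error = function(e) NA_real_
  )
  if (!is.finite(val)) return(NA_real_)
  min(max(val, 0), 1)
}

# connected components of the |r| = 1 graph (tolerance 1e-9)
perfect_ld_groups <- function(ld) {
  m <- nrow(ld)
  adj <- abs(ld) >= 1 - 1e-9
  seen <- logical(m)
  groups <- list()
  for (j in seq_len(m)) {
    if (seen[j]) next
    comp <- j
    frontier <- j
    seen[j] <- TRUE
    while (length(frontier)) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
      seen[nxt] <- TRUE
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    groups[[length(groups) + 1L]] <- sort(comp)
  }
  groups
}

#' Gene-level analysis across P-value thresholds
#'
#' Runs [gene_omnibus_test()] for every gene at every threshold of the
#' grid, with LD estimated from a reference genotype matrix (Pearson
#' correlation of mean-imputed dosages).  At each threshold only SNPs
#' strictly below that P ceiling enter the gene statistic; a gene with
#' no retained SNP at a threshold is absent from that threshold's
#' block.
#'
#' @param sumstats summary-statistics data frame.
#' @param annotation gene annotation data frame.
#' @param reference reference `genotype_matrix` for LD.
#' @param thresholds threshold grid from [threshold_config()].
#' @param ... passed to [map_snps_to_genes()].
#' @return data frame of gene results, one row per (gene, threshold).
#' @export
run_gene_analysis <- function(sumstats, annotation, reference,
                              thresholds = threshold_config(), ...) {
  gmap <- map_snps_to_genes(sumstats, annotation, ...)
  in_ref <- sumstats$snp_id %in% reference$variants$snp_id
  overlap <- mean(in_ref)
  if (overlap < 0.5) {
    warning(sprintf(
      "run_gene_analysis: reference panel covers only %.1f%% of summary-stat SNPs",
      100 * overlap), call. = FALSE)
  }
  ss <- sumstats[in_ref, , drop = FALSE]
  pv <- stats::setNames(ss$pvalue, ss$snp_id)
  # impute the reference once; LD per gene computed on the full SNP
  # set, thresholds subset it
  ref_dos <- mean_impute_dosages(reference)$dosages
  ref_idx <- stats::setNames(seq_len(nrow(reference$variants)),
                             reference$variants$snp_id)
  ld_cache <- lapply(gmap, function(snps) {
    snps <- intersect(snps, ss$snp_id)
    if (length(snps) < 2L) return(NULL)
    ld_from_dosages(ref_dos[, ref_idx[snps], drop = FALSE], snps)
  })
  out <- vector("list", length(thresholds) * length(gmap))
  k <- 0L
  for (p_t in thresholds) {
    for (g in names(gmap)) {
      snps <- intersect(gmap[[g]], ss$snp_id)
      if (p_t < 1) snps <- snps[pv[snps] < p_t]
      if (length(snps) == 0L) next
      ld <- if (length(snps) == 1L) NULL else
        ld_cache[[g]][snps, snps, drop = FALSE]
      k <- k + 1L
      out[[k]] <- gene_omnibus_test(pv[snps], ld, gene_id = g,
                                    p_threshold = p_t)
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}
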