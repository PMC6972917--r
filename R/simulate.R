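#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator.  Genotypes
#' are drawn as AR(1)-correlated latent-Gaussian haplotype pairs in LD
#' blocks; phenotypes follow an additive liability-threshold model with
#' effect variance concentrated in designated "enriched" pathways; the
#' GWAS is run on the simulated cohort itself, or on a separate
#' discovery cohort in two-cohort mode (which avoids winner's-curse
#' coupling between effect estimation and scoring, the structure of a
#' consortium GWAS applied to an independent target cohort).
#'
#' The default prevalence is 0.7%, the population value for a
#' schizophrenia-like trait; desk-scale presets override it upward so
#' case quotas are reachable from small simulated pools.
#'
#' @param n_individuals cohort size (ignored when case/control quotas
#'   are set).
#' @param n_snps,n_genes variant and gene counts (SNPs are spread
#'   evenly over gene bodies so each SNP maps to exactly one gene).
#' @param n_sets,set_size gene-set collection dimensions.
#' @param ld_block_size,ld_rho AR(1) LD block length and correlation.
#' @param maf_range allele-frequency sampling range.
#' @param enriched_sets indices of planted enriched sets (may be
#'   empty for a null generator).
#' @param enrichment_multiplier effect-variance multiplier for SNPs in
#'   enriched-set genes.
#' @param causal_fraction background fraction of causal SNPs.
#' @param h2 liability-scale heritability in (0,1).
#' @param prevalence liability-threshold prevalence in (0,1).
#' @param n_cases,n_controls optional case/control quotas for the
#'   emitted cohort (sampled from a larger pool).
#' @param two_cohort run the GWAS on a separate discovery cohort.
#' @param n_discovery discovery cohort size (two-cohort mode).
#' @param expression list: `n_samples` (cases with expression),
#'   `gamma` (planted standardised PES-expression slope),
#'   `noise_sd`, `n_affected` (genes per pathway with a true slope),
#'   `p_available` (probability a pathway gene is on the array).
#' @param seed integer seed fixing the full stream.
#' @export
sim_config <- function(n_individuals = 500, n_snps = 400, n_genes = 50,
                       n_sets = 10, set_size = 6, ld_block_size = 8,
                       ld_rho = 0.7, maf_range = c(0.05, 0.5),
                       enriched_sets = integer(0),
                       enrichment_multiplier = 25,
                       causal_fraction = 0.2, h2 = 0.45,
                       prevalence = 0.007,
                       n_cases = NULL, n_controls = NULL,
                       two_cohort = FALSE, n_discovery = 2000,
                       expression = list(n_samples = 50, gamma = 0.8,
                                         noise_sd = 1, n_affected = 2,
                                         p_available = 0.8),
                       seed = 1L) {
  stopifnot(n_snps >= n_genes, n_genes >= 1, n_sets >= 1,
            set_size <= n_genes, ld_block_size >= 1)
  if (ld_rho >= 1 || ld_rho < 0) stop_input("ld_rho must lie in [0,1)")
  if (h2 <= 0 || h2 >= 1) stop_input("h2 must lie in (0,1)")
  check_prob(prevalence, "prevalence", open_left = TRUE)
  structure(as.list(environment()), class = "sim_config")
}

#' Named simulation presets
#'
#' `mini`: small single-cohort design for fast checks.
#' `paper_shaped`: a consortium-style two-cohort design — a 4000-strong
#' discovery GWAS over 2000 SNPs in 250 genes, 50 druggable pathways of
#' which eight carry planted enrichment, and a 425-case / 251-control
#' target cohort with a 75-case expression subset.
#' `null`: the mini layout with no planted enrichment.
#'
#' @param name `"mini"`, `"paper_shaped"` or `"null"`.
#' @param seed integer seed.
#' @export
pes_preset <- function(name = c("mini", "paper_shaped", "null"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    mini = sim_config(n_individuals = 300, n_snps = 400, n_genes = 50,
                      n_sets = 10, set_size = 6, ld_block_size = 8,
                      ld_rho = 0.7, enriched_sets = 1L,
                      enrichment_multiplier = 25, h2 = 0.5,
                      prevalence = 0.4,
                      expression = list(n_samples = 60, gamma = 0.8,
                                        noise_sd = 1, n_affected = 2,
                                        p_available = 0.8),
                      seed = seed),
    paper_shaped = sim_config(n_individuals = 676, n_snps = 2000,
                              n_genes = 250, n_sets = 50, set_size = 8,
                              ld_block_size = 8, ld_rho = 0.8,
                              enriched_sets = 1:8,
                              enrichment_multiplier = 25,
                              causal_fraction = 0.2, h2 = 0.45,
                              prevalence = 0.35,
                              n_cases = 425, n_controls = 251,
                              two_cohort = TRUE, n_discovery = 4000,
                              expression = list(n_samples = 75, gamma = 0.8,
                                                noise_sd = 1, n_affected = 2,
                                                p_available = 0.8),
                              seed = seed),
    null = sim_config(n_individuals = 300, n_snps = 400, n_genes = 50,
                      n_sets = 10, set_size = 6, ld_block_size = 8,
                      ld_rho = 0.7, enriched_sets = integer(0),
                      h2 = 0.5, prevalence = 0.4, seed = seed)
  )
}

# Genome layout: genes of 4 kb placed every 20 kb on chromosome 1, so
# the 5 kb / 1.5 kb windows of neighbouring genes never overlap and
# every SNP maps to exactly one gene.
sim_gene_coords <- function(config) {
  g <- seq_len(config$n_genes)
  start <- (g - 1L) * 20000L + 10000L
  data.frame(gene_id = sprintf("G%04d", g), chrom = "1",
             start = start, end = start + 4000L,
             strand = rep(c("+", "-"), length.out = config$n_genes),
             stringsAsFactors = FALSE)
}

#' Synthetic gene annotation table
#' @param config a [sim_config()].
#' @export
simulate_annotation <- function(config) sim_gene_coords(config)

# SNP layout: n_snps spread over genes (earlier genes absorb the
# remainder), evenly spaced inside the 4 kb gene body.
sim_snp_layout <- function(config) {
  coords <- sim_gene_coords(config)
  per <- rep(config$n_snps %/% config$n_genes, config$n_genes)
  extra <- config$n_snps %% config$n_genes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  rows <- lapply(seq_len(config$n_genes), function(g) {
    m <- per[g]
    if (m == 0L) return(NULL)
    off <- round(seq(200, 3800, length.out = m))
    data.frame(gene_id = coords$gene_id[g], chrom = "1",
               pos = coords$start[g] + off, stringsAsFactors = FALSE)
  })
  snps <- do.call(rbind, rows)
  snps$snp_id <- sprintf("rs%05d", seq_len(nrow(snps)))
  snps
}

#' Simulate LD-block genotype dosages
#'
#' Within each block of `ld_block_size` consecutive SNPs, two latent
#' Gaussian haplotype vectors are drawn with AR(1) correlation
#' `ld_rho` and thresholded at the allele-frequency quantile; the
#' dosage is the haplotype sum.  Blocks are independent, so `ld_rho =
#' 0` gives independent SNPs and large `ld_rho` strong local LD.
#'
#' @param config a [sim_config()].
#' @param n number of individuals (default `config$n_individuals`).
#' @param stream integer stream offset so different cohorts drawn from
#'   one config are independent yet reproducible.
#' @return a [genotype_matrix()] whose variant table carries the
#'   `gene_id` each SNP belongs to and the true allele frequency
#'   `freq`; counted allele "A", other allele "G".
#' @export
simulate_genotypes <- function(config, n = NULL, stream = 1L) {
  n <- n %||% config$n_individuals
  snps <- sim_snp_layout(config)
  m <- nrow(snps)
  set.seed(derive_seed(config$seed, stream))
  freq <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  blocks <- split(seq_len(m), (seq_len(m) - 1L) %/% config$ld_block_size)
  dos <- matrix(0, n, m)
  chol_cache <- list()
  for (idx in blocks) {
    b <- length(idx)
    key <- as.character(b)
    if (is.null(chol_cache[[key]])) {
      chol_cache[[key]] <-
        chol(config$ld_rho^abs(outer(seq_len(b), seq_len(b), `-`)))
    }
    ch <- chol_cache[[key]]
    thr <- stats::qnorm(1 - freq[idx])
    for (h in 1:2) {
      z <- matrix(stats::rnorm(n * b), n, b) %*% ch
      dos[, idx] <- dos[, idx] + (sweep(z, 2, thr, `>`) * 1)
    }
  }
  variants <- data.frame(snp_id = snps$snp_id, chrom = snps$chrom,
                         pos = snps$pos, counted_allele = "A",
                         other_allele = "G", impute_score = NA_real_,
                         gene_id = snps$gene_id, freq = freq,
                         stringsAsFactors = FALSE)
  genotype_matrix(sprintf("S%05d", seq_len(n)), variants, dos)
}

#' Simulate a druggable gene-set collection
#'
#' Samples `n_sets` sets of `set_size` genes from the annotation
#' universe.  Sets listed in `config$enriched_sets` are the planted
#' enriched pathways (their genes carry inflated effect variance in
#' the phenotype model).  A druggable-gene list is drawn so every set
#' keeps at least one druggable gene and therefore survives
#' [flag_druggable()].
#'
#' @param config a [sim_config()].
#' @return list with `sets` (named list of [gene_set()]),
#'   `druggable_genes`, and `enriched_genes` (union over planted sets).
#' @export
simulate_gene_sets <- function(config) {
  set.seed(derive_seed(config$seed, 2L))
  genes <- sim_gene_coords(config)$gene_id
  sets <- lapply(seq_len(config$n_sets), function(i) {
    gene_set(sprintf("SET%03d", i),
             sprintf("synthetic pathway %d", i),
             sample(genes, config$set_size))
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  druggable <- unique(c(
    sample(genes, max(1L, round(0.3 * length(genes)))),
    vapply(sets, function(s) s$genes[[1]], character(1))
  ))
  enriched <- unique(unlist(lapply(config$enriched_sets,
                                   function(i) sets[[i]]$genes)))
  list(sets = sets, druggable_genes = druggable,
       enriched_genes = enriched %||% character(0))
}

#' Simulate a liability-threshold phenotype and run the GWAS
#'
#' True effects: SNPs mapped to enriched-set genes are causal with
#' variance `enrichment_multiplier`; background SNPs are causal with
#' probability `causal_fraction` and unit variance.  The genetic value
#' over standardised dosages is rescaled to heritability `h2`, unit
#' Gaussian environmental noise completes the liability, and an
#' individual is a case when the liability exceeds the
#' `1 - prevalence` quantile.  The GWAS is a per-SNP logistic
#' regression of case status on dosage over the (optionally
#' quota-sampled) cohort.
#'
#' @param gm a simulated `genotype_matrix` (variant table must carry
#'   `gene_id`).
#' @param config a [sim_config()].
#' @param enriched_genes genes whose SNPs carry inflated effects.
#' @param quota optional `c(n_cases, n_controls)`; the cohort is the
#'   first so-many cases and controls of `gm` (error when the pool has
#'   too few).
#' @param stream seed stream offset.
#' @return list: `phenotypes` (cohort covariate table), `sumstats`
#'   (GWAS summary statistics), `cohort_ids`, and `truth` (causal SNP
#'   effects, liabilities and pre-sampling labels).
#' @export
simulate_phenotype_and_gwas <- function(gm, config,
                                        enriched_genes = character(0),
                                        quota = NULL, stream = 3L) {
  n <- length(gm$samples)
  m <- nrow(gm$variants)
  # the true genetic architecture is a property of the configuration,
  # drawn from its own stream so that every cohort simulated from one
  # config (discovery and target) shares the same causal effects
  set.seed(derive_seed(config$seed, 101L))
  enriched_snp <- gm$variants$gene_id %in% enriched_genes
  causal <- enriched_snp | stats::runif(m) < config$causal_fraction
  b <- numeric(m)
  sdv <- ifelse(enriched_snp, sqrt(config$enrichment_multiplier), 1)
  b[causal] <- stats::rnorm(sum(causal)) * sdv[causal]
  set.seed(derive_seed(config$seed, stream))
  xs <- scale(gm$dosages)
  xs[is.na(xs)] <- 0                       # monomorphic columns
  g <- as.vector(xs %*% b)
  sg <- stats::sd(g)
  if (sg > 0) g <- g * sqrt(config$h2) / sg
  liability <- g + stats::rnorm(n, sd = sqrt(1 - config$h2))
  case <- as.integer(liability > stats::qnorm(1 - config$prevalence))
  if (!is.null(quota)) {
    ic <- which(case == 1L)[seq_len(quota[1])]
    iu <- which(case == 0L)[seq_len(quota[2])]
    if (anyNA(ic) || anyNA(iu)) {
      stop_input("pool too small for the case/control quota; enlarge n or prevalence")
    }
    cohort <- sort(c(ic, iu))
  } else {
    cohort <- seq_len(n)
  }
  y <- case[cohort]
  if (sum(y) < 10L) {
    stop_input("fewer than 10 cases sampled; increase n or prevalence")
  }
  gwas <- fast_logistic_gwas(y, gm$dosages[cohort, , drop = FALSE])
  sumstats <- data.frame(
    snp_id = gm$variants$snp_id, chrom = gm$variants$chrom,
    pos = gm$variants$pos,
    effect_allele = gm$variants$counted_allele,
    other_allele = gm$variants$other_allele,
    beta = gwas$beta, pvalue = gwas$pvalue, stringsAsFactors = FALSE
  )
  ids <- gm$samples[cohort]
  phenotypes <- data.frame(
    sample_id = ids, case_status = y,
    sex = stats::rbinom(length(ids), 1, 0.5),
    age = round(stats::rnorm(length(ids), 42.2, 10.5), 1),
    PC1 = stats::rnorm(length(ids)), PC2 = stats::rnorm(length(ids)),
    PC3 = stats::rnorm(length(ids)), stringsAsFactors = FALSE
  )
  truth <- list(
    causal = data.frame(snp_id = gm$variants$snp_id[causal],
                        beta_true = b[causal], stringsAsFactors = FALSE),
    enriched_genes = enriched_genes,
    liability = liability, case_pre_sampling = case
  )
  list(phenotypes = phenotypes, sumstats = sumstats,
       cohort_ids = ids, truth = truth)
}

# pool large enough that the case/control quota is met with margin
quota_pool_size <- function(quota, config) {
  if (is.null(quota)) return(config$n_individuals)
  ceiling(1.5 * max(quota[1] / config$prevalence,
                    quota[2] / (1 - config$prevalence)))
}

# per-SNP logistic GWAS: Wald beta/SE/P for the dosage term, fitted by
# Newton-Raphson vectorised across all SNPs at once (each model is an
# intercept plus one dosage column, so the per-SNP Hessian is 2x2 and
# every quantity reduces to a column sum)
fast_logistic_gwas <- function(y, dosages) {
  n <- nrow(dosages)
  m <- ncol(dosages)
  g <- dosages
  nas <- which(is.na(g), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    mu <- colMeans(g, na.rm = TRUE)
    g[nas] <- mu[nas[, 2]]
  }
  ok <- col_vars(g) > 0
  g2 <- g * g
  b0 <- rep(stats::qlogis(mean(y)), m)
  b1 <- numeric(m)
  h00 <- h01 <- h11 <- det <- rep(NA_real_, m)
  for (it in 1:40) {
    eta <- pmin(pmax(g * rep(b1, each = n) + rep(b0, each = n), -30), 30)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    r <- y - p
    g0 <- colSums(r)
    g1 <- colSums(g * r)
    h00 <- colSums(w)
    h01 <- colSums(g * w)
    h11 <- colSums(g2 * w)
    det <- h00 * h11 - h01^2
    det[!ok | det <= 0] <- NA_real_
    db0 <- (h11 * g0 - h01 * g1) / det
    db1 <- (h00 * g1 - h01 * g0) / det
    db0[is.na(db0)] <- 0
    db1[is.na(db1)] <- 0
    b0 <- b0 + db0
    b1 <- b1 + db1
    if (max(abs(db0), abs(db1)) < 1e-10) break
  }
  se <- sqrt(h00 / det)
  z <- b1 / se
  pval <- 2 * stats::pnorm(-abs(z))
  bad <- !ok | !is.finite(se) | se <= 0 | se > 100 | !is.finite(pval)
  b1[bad] <- 0
  pval[bad] <- 1
  pval[pval <= 0] <- .Machine$double.xmin
  list(beta = b1, pvalue = pval)
}

# column variances without an extra dependency
col_vars <- function(x) {
  n <- nrow(x)
  (colSums(x * x) - colSums(x)^2 / n) / (n - 1)
}

#' Simulate a drug-gene interaction table
#'
#' Synthetic drugs each target a random handful of genes; drugs whose
#' targets hit a druggable gene are mostly flagged approved and given
#' a toy ATC code.  One "focused" drug per enriched set targets several
#' genes of that set, so over-representation has something to find.
#'
#' @param config a [sim_config()].
#' @param sets named list of gene sets.
#' @param druggable_genes druggable-gene list.
#' @param n_drugs number of background drugs (default 40).
#' @export
simulate_drug_interactions <- function(config, sets, druggable_genes,
                                       n_drugs = 40) {
  set.seed(derive_seed(config$seed, 5L))
  genes <- sim_gene_coords(config)$gene_id
  rows <- list()
  add <- function(drug, targets, approved, atc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      drug_name = drug, gene_id = unique(targets),
      interaction_score = round(stats::runif(length(unique(targets)),
                                             0.05, 1), 3),
      approved = approved, atc_code = atc, stringsAsFactors = FALSE)
  }
  atcs <- c("N05A", "N06A", "A10B", "L01X", "B03B", "M01A", "S01E", "C09A")
  for (d in seq_len(n_drugs)) {
    add(sprintf("drug%03d", d), sample(genes, sample(2:8, 1)),
        stats::runif(1) < 0.7, sample(atcs, 1))
  }
  for (i in config$enriched_sets) {
    s <- sets[[i]]
    k <- min(length(s$genes), max(3L, length(s$genes) - 2L))
    add(sprintf("focus_%s", tolower(s$name)), sample(s$genes, k),
        TRUE, sample(atcs, 1))
  }
  out <- do.call(rbind, rows)
  out[!duplicated(out[, c("drug_name", "gene_id")]), , drop = FALSE]
}

#' Simulate PES-linked expression
#'
#' For a subset of case individuals, expression of each available
#' pathway gene is `alpha_g + gamma_g * PES_std + 0.01 * age + noise`,
#' where `gamma_g` equals `config$expression$gamma` for the first
#' `n_affected` genes of each pathway (slope on the standardised
#' pathway score) and 0 otherwise.
#'
#' @param scores score matrix with one column per pathway.
#' @param phenotypes phenotype table covering the score rows.
#' @param pathways named list of gene sets (or candidates frame).
#' @param config a [sim_config()].
#' @return list: `expression` (genes x samples), `truth` (data frame
#'   of planted slopes per pathway-gene pair).
#' @export
simulate_expression <- function(scores, phenotypes, pathways, config) {
  set.seed(derive_seed(config$seed, 6L))
  ex_cfg <- config$expression
  path_genes <- pathway_gene_list(pathways)
  cases <- phenotypes$sample_id[phenotypes$case_status == 1L]
  cases <- intersect(cases, rownames(scores))
  samples <- cases[seq_len(min(ex_cfg$n_samples, length(cases)))]
  genes <- unique(unlist(path_genes, use.names = FALSE))
  genes <- genes[stats::runif(length(genes)) < (ex_cfg$p_available %||% 1)]
  age <- phenotypes$age[match(samples, phenotypes$sample_id)]
  truth <- list()
  expr <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
  slopes <- stats::setNames(numeric(length(genes)), genes)
  for (pw in names(path_genes)) {
    if (!pw %in% colnames(scores)) next
    avail <- intersect(path_genes[[pw]], genes)
    aff <- utils::head(avail, ex_cfg$n_affected %||% 0L)
    for (g in aff) slopes[g] <- slopes[g] + ex_cfg$gamma
    truth[[pw]] <- data.frame(pathway = pw, gene = avail,
                              gamma = ifelse(avail %in% aff,
                                             ex_cfg$gamma, 0),
                              stringsAsFactors = FALSE)
  }
  # build expression gene-wise: slope applies on the (first) pathway
  # score of each affected gene
  gene_pw <- stats::setNames(rep(NA_character_, length(genes)), genes)
  for (pw in rev(names(path_genes))) {
    gene_pw[intersect(path_genes[[pw]], genes)] <- pw
  }
  for (g in genes) {
    pw <- gene_pw[[g]]
    s <- scores[samples, pw]
    s_std <- if (stats::sd(s) > 0) (s - mean(s)) / stats::sd(s) else s * 0
    expr[g, ] <- stats::rnorm(1, 8, 1) + slopes[[g]] * s_std +
      0.01 * age + stats::rnorm(length(samples), sd = ex_cfg$noise_sd)
  }
  list(expression = expr, truth = do.call(rbind, truth))
}

#' Run the full synthetic study
#'
#' Orchestrates the generator: gene sets, a discovery cohort GWAS
#' (separate in two-cohort mode), and a quota-sampled target cohort
#' with genotypes and covariates.  Everything downstream of the
#' generator — gene analysis, set association, scoring, profiling —
#' consumes these outputs through the same interfaces as real data.
#'
#' @param config a [sim_config()].
#' @return list: `annotation`, `sets`, `druggable_genes`,
#'   `enriched_genes`, `sumstats`, `gm` (target cohort genotypes),
#'   `phenotypes`, `truth`, `interactions`.
#' @export
simulate_study <- function(config) {
  ann <- simulate_annotation(config)
  gs <- simulate_gene_sets(config)
  quota <- if (!is.null(config$n_cases)) c(config$n_cases, config$n_controls)
  if (config$two_cohort) {
    disc <- simulate_genotypes(config, n = config$n_discovery, stream = 11L)
    gwas <- simulate_phenotype_and_gwas(disc, config, gs$enriched_genes,
                                        stream = 13L)
    pool_n <- quota_pool_size(quota, config)
    pool <- simulate_genotypes(config, n = pool_n, stream = 21L)
    target <- simulate_phenotype_and_gwas(pool, config, gs$enriched_genes,
                                          quota = quota, stream = 23L)
    keep <- match(target$cohort_ids, pool$samples)
    gm <- genotype_matrix(target$cohort_ids,
                          pool$variants,
                          pool$dosages[keep, , drop = FALSE])
    sumstats <- gwas$sumstats
    truth <- gwas$truth
    phenotypes <- target$phenotypes
  } else {
    pool_n <- quota_pool_size(quota, config)
    pool <- simulate_genotypes(config, n = pool_n, stream = 11L)
    res <- simulate_phenotype_and_gwas(pool, config, gs$enriched_genes,
                                       quota = quota, stream = 13L)
    keep <- match(res$cohort_ids, pool$samples)
    gm <- genotype_matrix(res$cohort_ids, pool$variants,
                          pool$dosages[keep, , drop = FALSE])
    sumstats <- res$sumstats
    truth <- res$truth
    phenotypes <- res$phenotypes
  }
  interactions <- simulate_drug_interactions(config, gs$sets,
                                             gs$druggable_genes)
  list(annotation = ann, sets = gs$sets,
       druggable_genes = gs$druggable_genes,
       enriched_genes = gs$enriched_genes,
       sumstats = sumstats, gm = gm, phenotypes = phenotypes,
       truth = truth, interactions = interactions)
}

#' Write a complete fixture suite to disk
#'
#' Emits every input the pipeline consumes: summary statistics,
#' annotation, GMT, druggable-gene list, drug interactions, genotypes
#' (dosage VCF and PLINK bed/bim/fam), phenotypes, an expression
#' matrix over the planted pathways, and a ground-truth JSON.
#'
#' @param config a [sim_config()].
#' @param outdir output directory.
#' @param force overwrite a non-empty directory.
#' @return invisible named vector of written paths.
#' @export
write_fixture_suite <- function(config, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force) {
    stop_input("output directory not empty (use force = TRUE): ", outdir)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(config)
  p <- function(f) file.path(outdir, f)
  write_summary_stats(study$sumstats, p("sumstats.tsv"))
  write_gene_annotation(study$annotation, p("annotation.tsv"))
  write_gene_sets_gmt(study$sets, p("sets.gmt"))
  writeLines(study$druggable_genes, p("druggable_genes.txt"))
  utils::write.table(study$interactions, p("drug_interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_genotypes_vcf(study$gm, p("genotypes.vcf"))
  write_genotypes_plink(study$gm, p("genotypes"), study$phenotypes)
  write_phenotypes(study$phenotypes, p("phenotypes.tsv"))
  # expression over the planted sets' pathway scores requires scores;
  # use raw per-pathway sums of harmonised effects as the linked score
  pathway_list <- study$sets[config$enriched_sets %||% integer(0)]
  if (length(pathway_list) > 0) {
    gmap <- suppressWarnings(
      map_snps_to_genes(study$sumstats, study$annotation)
    )
    defs <- list()
    h <- suppressMessages(harmonise_alleles(study$sumstats, study$gm))
    for (s in pathway_list) {
      snps <- intersect(unlist(gmap[intersect(s$genes, names(gmap))],
                               use.names = FALSE), h$snp_id)
      if (length(snps) == 0) next
      hh <- h[h$snp_id %in% snps, , drop = FALSE]
      defs[[s$name]] <- score_definition(s$name, hh$snp_id, hh$beta,
                                         pathway = s$name)
    }
    if (length(defs) > 0) {
      scores <- suppressMessages(score_matrix(defs, study$gm))
      ex <- simulate_expression(scores, study$phenotypes,
                                study$sets[names(defs)], config)
      write_expression(ex$expression, p("expression.tsv"))
      study$truth$expression <- ex$truth
    }
  }
  truth <- study$truth
  truth$liability <- NULL                  # bulky; labels retained
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- dir(outdir, full.names = TRUE)
  invisible(stats::setNames(files, basename(files)))
}
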