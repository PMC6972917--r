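test_that("genotype simulation hits target frequencies and LD structure", {
  cfg0 <- sim_config(n_individuals = 1000, n_snps = 100, n_genes = 20,
                     n_sets = 2, set_size = 3, ld_block_size = 5,
                     ld_rho = 0, prevalence = 0.4, seed = 101)
  gm0 <- simulate_genotypes(cfg0)
  # independence limit: mean absolute off-diagonal correlation is small
  r <- cor(gm0$dosages)
  expect_lt(mean(abs(r[upper.tri(r)])), 0.1)
  # empirical frequency tracks the target
  freq_hat <- colMeans(gm0$dosages) / 2
  expect_lt(max(abs(freq_hat - gm0$variants$freq)), 0.05)

  cfg9 <- sim_config(n_individuals = 1000, n_snps = 50, n_genes = 10,
                     n_sets = 2, set_size = 3, ld_block_size = 10,
                     ld_rho = 0.9, prevalence = 0.4, seed = 102)
  gm9 <- simulate_genotypes(cfg9)
  d <- gm9$dosages
  adj <- vapply(seq_len(49), function(j) {
    if ((j %% 10) == 0) NA_real_ else cor(d[, j], d[, j + 1])
  }, numeric(1))
  expect_gt(mean(adj, na.rm = TRUE), 0.4)

  # full determinism under a fixed seed
  gm_again <- simulate_genotypes(cfg9)
  expect_identical(gm_again$dosages, gm9$dosages)
})

test_that("null GWAS is calibrated (lambda_GC near 1, case rate near K)", {
  cfg <- sim_config(n_individuals = 800, n_snps = 5000, n_genes = 625,
                    n_sets = 2, set_size = 5, ld_block_size = 4,
                    ld_rho = 0.5, h2 = 0.01, causal_fraction = 0,
                    prevalence = 0.5, seed = 103)
  gm <- simulate_genotypes(cfg)
  sim <- simulate_phenotype_and_gwas(gm, cfg, character(0))
  chi <- qchisq(sim$sumstats$pvalue, df = 1, lower.tail = FALSE)
  lambda <- median(chi) / qchisq(0.5, df = 1)
  expect_gt(lambda, 0.9); expect_lt(lambda, 1.1)
  frac <- mean(sim$phenotypes$case_status)
  expect_lt(abs(frac - 0.5), 2.58 * sqrt(0.25 / 800))
})

test_that("a single strong causal SNP attains the minimum P", {
  wins <- 0L
  for (r in 1:10) {
    cfg <- sim_config(n_individuals = 500, n_snps = 60, n_genes = 10,
                      n_sets = 2, set_size = 3, ld_block_size = 3,
                      ld_rho = 0.3, h2 = 0.35, causal_fraction = 0,
                      enrichment_multiplier = 1, prevalence = 0.4,
                      enriched_sets = integer(0), seed = 1030 + r)
    gm <- simulate_genotypes(cfg)
    # one enriched gene = one strong causal block of SNPs; restrict to
    # a single-SNP gene by picking a gene with its SNPs and using the
    # first gene's id
    target_gene <- gm$variants$gene_id[1]
    cfg$enrichment_multiplier <- 50
    sim <- simulate_phenotype_and_gwas(gm, cfg, enriched_genes = target_gene)
    top <- sim$sumstats$snp_id[which.min(sim$sumstats$pvalue)]
    if (top %in% gm$variants$snp_id[gm$variants$gene_id == target_gene]) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 9L)
})

test_that("expression generator plants recoverable slopes", {
  set.seed(104)
  cfg <- pes_preset("mini", seed = 104)
  ids <- sprintf("S%05d", 1:80)
  scores <- cbind(SET001 = rnorm(80), PRS_TOTAL = rnorm(80))
  rownames(scores) <- ids
  pheno <- data.frame(sample_id = ids, case_status = 1L,
                      sex = rbinom(80, 1, 0.5), age = rnorm(80, 42, 10))
  sets <- simulate_gene_sets(cfg)$sets["SET001"]
  # noiseless limit: correlation approaches 1 for affected genes
  cfg$expression$noise_sd <- 1e-6
  cfg$expression$gamma <- 1
  ex <- simulate_expression(scores, pheno, sets, cfg)
  aff <- ex$truth$gene[ex$truth$gamma > 0]
  for (g in aff) {
    expect_gt(abs(cor(ex$expression[g, ],
                      scores[colnames(ex$expression), "SET001"])), 0.99)
  }
  # gamma = 0: correlations centred on zero
  cfg$expression$gamma <- 0
  cfg$expression$noise_sd <- 1
  ex0 <- simulate_expression(scores, pheno, sets, cfg)
  cors <- apply(ex0$expression, 1, function(e) {
    cor(e, scores[colnames(ex0$expression), "SET001"])
  })
  expect_lt(abs(mean(cors)), 0.15)
})

test_that("the fixture suite round-trips through the readers", {
  out <- file.path(withr::local_tempdir(), "fx")
  cfg <- sim_config(n_individuals = 120, n_snps = 120, n_genes = 20,
                    n_sets = 5, set_size = 4, ld_block_size = 6,
                    ld_rho = 0.6, enriched_sets = 1L, h2 = 0.5,
                    prevalence = 0.4,
                    expression = list(n_samples = 30, gamma = 0.8,
                                      noise_sd = 1, n_affected = 2,
                                      p_available = 1),
                    seed = 105)
  files <- suppressMessages(suppressWarnings(write_fixture_suite(cfg, out)))
  expect_error(write_fixture_suite(cfg, out), "not empty")

  ss <- read_summary_stats(file.path(out, "sumstats.tsv"), sep = "\t")
  expect_equal(nrow(ss), 120)
  ann <- read_gene_annotation(file.path(out, "annotation.tsv"))
  expect_equal(nrow(ann), 20)
  sets <- read_gene_sets_gmt(file.path(out, "sets.gmt"))
  expect_length(sets, 5)
  ints <- read_drug_interactions(file.path(out, "drug_interactions.tsv"))
  expect_true(nrow(ints) > 0)
  ph <- read_phenotypes(file.path(out, "phenotypes.tsv"))
  gm_v <- read_genotypes(file.path(out, "genotypes.vcf"), "vcf")
  gm_p <- read_genotypes(file.path(out, "genotypes"), "plink")
  expect_equal(gm_v$samples, ph$sample_id)
  expect_equal(gm_p$samples, ph$sample_id)
  expect_equal(gm_v$variants$snp_id, gm_p$variants$snp_id)
  # VCF dosages carry the exact values; PLINK rounds to hard calls
  expect_equal(unname(gm_p$dosages), unname(round(gm_v$dosages)))
  expr <- read_expression(file.path(out, "expression.tsv"))
  expect_true(all(colnames(expr) %in% ph$sample_id))
  truth <- jsonlite::read_json(file.path(out, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_true(all(truth$causal$snp_id %in% ss$snp_id))
  expect_equal(nrow(truth$causal),
               length(unique(truth$causal$snp_id)))
})

test_that("planted enrichment drives candidate selection monotonically", {
  rates <- vapply(c(1, 8, 40), function(mult) {
    hits <- 0L
    for (r in 1:5) {
      cfg <- sim_config(n_individuals = 600, n_snps = 400, n_genes = 50,
                        n_sets = 10, set_size = 6, ld_block_size = 8,
                        ld_rho = 0.7, enriched_sets = 1L,
                        enrichment_multiplier = mult, h2 = 0.5,
                        prevalence = 0.4, seed = 1050 + r)
      study <- suppressMessages(suppressWarnings(simulate_study(cfg)))
      gene_res <- suppressWarnings(
        run_gene_analysis(study$sumstats, study$annotation, study$gm))
      tab <- suppressMessages(
        run_set_analysis(gene_res, flag_druggable(study$sets,
                                                  study$druggable_genes)$retained))
      cand <- select_candidates(tab, alpha = 0.001)
      if ("SET001" %in% cand$set_name) hits <- hits + 1L
    }
    hits / 5
  }, numeric(1))
  expect_true(rates[1] <= rates[2] || rates[2] <= rates[3])
  expect_gte(rates[3], rates[1])
})
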