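test_that("clumping keeps the index SNP and honours the window", {
  # two SNPs 10 kb apart in strong LD: only the smaller P survives
  set.seed(51)
  base <- rnorm(200)
  d <- cbind(pmin(pmax(round(base + 1), 0), 2),
             pmin(pmax(round(base + rnorm(200, sd = 0.4) + 1), 0), 2))
  gm <- toy_gm(d, pos = c(10000, 20000))
  stopifnot(cor(d)[1, 2]^2 > 0.5)
  ss <- toy_sumstats(c("snp01", "snp02"), pvalue = c(1e-8, 1e-4),
                     pos = c(10000, 20000))
  expect_equal(ld_clump(ss, gm, r2 = 0.1, window_kb = 250), "snp01")
  # same LD but 300 kb apart: outside the window, both retained
  gm2 <- toy_gm(d, pos = c(10000, 310000))
  ss2 <- toy_sumstats(c("snp01", "snp02"), pvalue = c(1e-8, 1e-4),
                      pos = c(10000, 310000))
  expect_setequal(ld_clump(ss2, gm2, r2 = 0.1, window_kb = 250),
                  c("snp01", "snp02"))
})

test_that("clump output satisfies the post-condition oracle and is order invariant", {
  set.seed(52)
  cfg <- sim_config(n_individuals = 300, n_snps = 200, n_genes = 25,
                    n_sets = 2, set_size = 3, ld_block_size = 10,
                    ld_rho = 0.8, prevalence = 0.4, seed = 52)
  gm <- simulate_genotypes(cfg)
  ss <- toy_sumstats(gm$variants$snp_id, pvalue = runif(200),
                     pos = gm$variants$pos)
  kept <- ld_clump(ss, gm, r2 = 0.1, window_kb = 50)
  dos <- gm$dosages
  r2mat <- cor(dos)^2
  pos <- setNames(gm$variants$pos, gm$variants$snp_id)
  pv <- setNames(ss$pvalue, ss$snp_id)
  window <- 50 * 1000
  # no retained pair may violate the rule
  for (a in kept) for (b in kept) {
    if (a != b && abs(pos[a] - pos[b]) <= window) {
      expect_lte(r2mat[a, b], 0.1)
    }
  }
  # every removed SNP violates it against some better retained index
  for (s in setdiff(ss$snp_id, kept)) {
    culprit <- any(vapply(kept, function(k) {
      abs(pos[k] - pos[s]) <= window && r2mat[k, s] > 0.1 &&
        (pv[k] < pv[s] || (pv[k] == pv[s] && k < s))
    }, logical(1)))
    expect_true(culprit, label = paste("removed SNP justified:", s))
  }
  # row order of the input must not matter
  perm <- sample(nrow(ss))
  expect_setequal(ld_clump(ss[perm, ], gm, r2 = 0.1, window_kb = 50), kept)
})

test_that("score computation matches the naive double loop exactly", {
  expect_equal(
    compute_score(score_definition("s", "snp01", log(2)),
                  toy_gm(matrix(c(2, 0), 2, 1))),
    c(2 * log(2), 0), ignore_attr = TRUE)

  set.seed(53)
  n <- 50; m <- 200
  d <- matrix(runif(n * m, 0, 2), n, m)
  gm <- toy_gm(d)
  beta <- rnorm(m)
  defn <- score_definition("rand", gm$variants$snp_id, beta)
  s <- compute_score(defn, gm)
  naive <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    naive[i] <- naive[i] + beta[j] * d[i, j]
  }
  expect_equal(s, naive, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("scores are linear in dosages and invariant to SNP order", {
  set.seed(54)
  n <- 20; m <- 30
  d1 <- matrix(runif(n * m), n, m); d2 <- matrix(runif(n * m), n, m)
  beta <- rnorm(m)
  ids <- sprintf("snp%02d", 1:m)
  defn <- score_definition("lin", ids, beta)
  s1 <- compute_score(defn, toy_gm(d1))
  s2 <- compute_score(defn, toy_gm(d2))
  s12 <- compute_score(defn, toy_gm(d1 + d2))
  expect_equal(s12, s1 + s2, tolerance = 1e-10, ignore_attr = TRUE)
  perm <- sample(m)
  defn_p <- score_definition("perm", ids[perm], beta[perm])
  expect_equal(compute_score(defn_p, toy_gm(d1)), s1,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("missing dosages are mean-imputed and absent scores error", {
  d <- matrix(c(0, 2, NA, 1, 1, 1), 3, 2)
  gm <- toy_gm(d)
  defn <- score_definition("s", c("snp01", "snp02"), c(1, 1))
  s <- compute_score(defn, gm)
  expect_equal(s, c(1, 3, 2), ignore_attr = TRUE)     # NA -> mean(0,2) = 1
  bad <- score_definition("none", "absent", 1)
  expect_error(compute_score(bad, gm), "no SNPs")
})

test_that("PES definitions respect threshold, clump and map constraints", {
  set.seed(55)
  cfg <- pes_preset("mini", seed = 55)
  study <- suppressMessages(simulate_study(cfg))
  gmap <- map_snps_to_genes(study$sumstats, study$annotation)
  gene_res <- run_gene_analysis(study$sumstats, study$annotation, study$gm)
  sets_flagged <- flag_druggable(study$sets, study$druggable_genes)
  tab <- suppressMessages(run_set_analysis(gene_res, sets_flagged$retained))
  cand <- select_candidates(tab, sets = study$sets, alpha = 0.05)
  expect_gt(nrow(cand), 0)
  defs <- suppressMessages(suppressWarnings(
    build_pes_definitions(cand, study$sumstats, gmap, study$gm)))
  pv <- setNames(study$sumstats$pvalue, study$sumstats$snp_id)
  for (nm in names(defs)) {
    d <- defs[[nm]]
    row <- cand[cand$set_name == nm, ]
    allowed <- unique(unlist(gmap[intersect(row$genes[[1]], names(gmap))]))
    expect_true(all(d$snp_id %in% allowed))
    if (row$p_threshold < 1) {
      expect_true(all(pv[d$snp_id] < row$p_threshold))
    }
  }
  # a pathway whose threshold excludes every SNP is skipped
  cand2 <- cand[1, ]
  cand2$p_threshold <- min(pv[unlist(gmap[intersect(cand2$genes[[1]],
                                                    names(gmap))])]) / 2
  expect_warning(
    d2 <- suppressMessages(
      build_pes_definitions(cand2, study$sumstats, gmap, study$gm)),
    "skipped")
  expect_length(d2, 0)
})

test_that("PES equals the genome-wide score restricted to its SNPs", {
  set.seed(56)
  n <- 40; m <- 60
  d <- matrix(runif(n * m, 0, 2), n, m)
  gm <- toy_gm(d)
  beta <- rnorm(m)
  ids <- gm$variants$snp_id
  sub <- sample(m, 15)
  pes <- compute_score(score_definition("p", ids[sub], beta[sub]), gm)
  restricted <- compute_score(
    score_definition("r", ids[sub], beta[sub], pathway = "TOTAL"), gm)
  expect_equal(pes, restricted, ignore_attr = TRUE)
})

test_that("Nagelkerke R2 matches the closed form and its boundaries", {
  expect_equal(nagelkerke_r2(-5, -5, 10), 0)
  expect_equal(nagelkerke_r2(2 * log(0.5), 0, 2), 1)
  expect_error(nagelkerke_r2(0, 0, 5), "saturated")
  set.seed(57)
  for (r in 1:20) {
    n <- 20
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    x <- rnorm(n) + y
    full <- glm(y ~ x, family = binomial())
    null <- glm(y ~ 1, family = binomial())
    l1 <- as.numeric(logLik(full)); l0 <- as.numeric(logLik(null))
    ref <- (1 - exp((2 / n) * (l0 - l1))) / (1 - exp((2 / n) * l0))
    expect_equal(nagelkerke_r2(l0, l1, n), ref, tolerance = 1e-10)
  }
})

test_that("PRS optimisation is null-calibrated and recovers planted signal", {
  set.seed(58)
  cfg <- sim_config(n_individuals = 500, n_snps = 200, n_genes = 25,
                    n_sets = 2, set_size = 3, ld_block_size = 8,
                    ld_rho = 0.6, h2 = 0.3, prevalence = 0.4, seed = 58)
  gm <- simulate_genotypes(cfg)
  # phenotype independent of genotype: R2 increments stay tiny
  pheno <- data.frame(sample_id = gm$samples,
                      case_status = rbinom(500, 1, 0.5),
                      sex = rbinom(500, 1, 0.5))
  ss <- toy_sumstats(gm$variants$snp_id, pvalue = runif(200),
                     beta = rnorm(200, sd = 0.05), pos = gm$variants$pos)
  opt <- suppressMessages(optimise_total_prs(ss, gm, pheno))
  expect_true(all(opt$grid$r2 < 0.05))
  expect_equal(opt$chosen_p_t, opt$grid$p_t[which.max(opt$grid$r2)])
  # a grid of size one chooses that threshold
  opt1 <- suppressMessages(optimise_total_prs(ss, gm, pheno, grid = 0.2))
  expect_equal(opt1$chosen_p_t, 0.2)
  expect_error(
    optimise_total_prs(ss, gm, transform(pheno, case_status = 1L)),
    "single class")
})

test_that("PRS threshold optimisation concentrates on the signal thresholds", {
  # planted architecture: all true signal sits below P = 1e-3 in the
  # discovery statistics; weaker-threshold SNPs carry pure noise, so
  # widening the ceiling dilutes the score on an independent cohort
  hits <- 0L
  for (r in 1:10) {
    set.seed(590 + r)
    cfg <- sim_config(n_individuals = 600, n_snps = 300, n_genes = 30,
                      n_sets = 2, set_size = 3, ld_block_size = 5,
                      ld_rho = 0.5, prevalence = 0.4, seed = 590 + r)
    gm <- simulate_genotypes(cfg)
    causal <- sample(300, 15)
    b <- numeric(300)
    b[causal] <- rnorm(15, sd = 0.35)
    g <- scale(gm$dosages) %*% b
    liab <- as.vector(g) + rnorm(600, sd = sqrt(max(1 - var(as.vector(g)), 0.2)))
    y <- as.integer(liab > quantile(liab, 0.5))
    pheno <- data.frame(sample_id = gm$samples, case_status = y,
                        sex = rbinom(600, 1, 0.5))
    ss <- toy_sumstats(gm$variants$snp_id,
                       pvalue = runif(300, 0.01, 1),
                       pos = gm$variants$pos)
    ss$beta <- rnorm(300, sd = 0.03)
    ss$pvalue[causal] <- runif(15, 1e-8, 1e-4)
    ss$beta[causal] <- b[causal]
    opt <- suppressMessages(
      optimise_total_prs(ss, gm, pheno,
                         grid = c(1e-3, 0.01, 0.1, 0.5, 1)))
    if (opt$chosen_p_t <= 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
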