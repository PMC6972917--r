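test_that("odds-ratio columns are log-transformed and invalid rows dropped", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tBP\tA1\tA2\tOR\tP",
               "rs1\t1\t100\tA\tG\t1.0\t0.5",
               "rs2\t1\t200\tC\tG\t2.0\t0.1",
               "rs3\t1\t300\tA\tC\t0.5\t0.9",
               "rs4\t1\t400\tA\tG\t1.5\t0"), f)
  ss <- suppressMessages(read_summary_stats(
    f, column_map = list(snp_id = "SNP", chrom = "CHR", pos = "BP",
                         effect_allele = "A1", other_allele = "A2",
                         or = "OR", pvalue = "P"), sep = "\t"))
  expect_equal(ss$beta, c(0, log(2), -log(2)))
  expect_equal(attr(ss, "n_dropped"), 1L)  # the P = 0 row
  expect_equal(nrow(ss), 3L)
})

test_that("summary statistics round-trip through write-then-read", {
  set.seed(11)
  ss <- toy_sumstats(sprintf("rs%d", 1:5), pvalue = runif(5),
                     beta = rnorm(5))
  ss$effect_allele <- c("A", "C", "A", "G", "T")
  ss$other_allele <- c("G", "T", "C", "A", "C")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, f)
  back <- read_summary_stats(f, sep = "\t")
  for (cn in names(ss)) expect_equal(back[[cn]], ss[[cn]], info = cn)
})

test_that("missing mandatory columns raise a configuration error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tP", "rs1\t0.5"), f)
  expect_error(read_summary_stats(f, sep = "\t"), "mandatory column")
})

test_that("GMT parsing deduplicates genes and counts sets exactly", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines("S1\tdesc\tA\tB\tA", f)
  sets <- read_gene_sets_gmt(f)
  expect_length(sets, 1)
  expect_setequal(sets$S1$genes, c("A", "B"))

  writeLines(character(0), f)
  expect_length(read_gene_sets_gmt(f), 0)

  writeLines("S1\tdesc_only", f)
  expect_error(read_gene_sets_gmt(f), "line 1")

  # a generator-written collection parses back with a known count
  big <- lapply(seq_len(1012), function(i) {
    gene_set(sprintf("SET%04d", i), "d", sprintf("G%d_%d", i, 1:4))
  })
  write_gene_sets_gmt(big, f)
  expect_length(read_gene_sets_gmt(f), 1012)
})

test_that("druggable flagging equals the set-intersection oracle", {
  s1 <- gene_set("s1", "", c("A", "B"))
  s2 <- gene_set("s2", "", c("A", "B"))
  r <- flag_druggable(list(s1 = s1), "B")
  expect_length(r$retained, 1)
  expect_equal(r$retained$s1$druggable_genes, "B")
  expect_length(flag_druggable(list(s2 = s2), "C")$retained, 0)

  set.seed(5)
  universe <- sprintf("G%02d", 1:40)
  sets <- lapply(1:10, function(i) {
    gene_set(paste0("S", i), "", sample(universe, 5))
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  druggable <- sample(universe, 8)
  res <- flag_druggable(sets, druggable)
  manual_keep <- vapply(sets, function(s) {
    length(intersect(s$genes, druggable)) > 0
  }, logical(1))
  expect_setequal(names(res$retained), names(sets)[manual_keep])
  for (s in res$retained) {
    expect_setequal(s$druggable_genes, intersect(s$genes, druggable))
  }
})

test_that("VCF genotypes read GT as ALT counts and DS verbatim", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ti1\ti2\ti3",
    "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1"), f)
  gm <- read_genotypes(f, "vcf")
  expect_equal(unname(gm$dosages[, 1]), c(0, 1, 2))
  expect_equal(gm$variants$counted_allele, "A")

  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ti1",
    "1\t100\trs1\tG\tA\t.\tPASS\t.\tDS\t0.37"), f)
  gm <- read_genotypes(f, "vcf")
  expect_identical(unname(gm$dosages[1, 1]), 0.37)
})

test_that("dosage VCF writer round-trips through the reader", {
  set.seed(3)
  gm <- toy_gm(matrix(round(runif(40, 0, 2), 3), 5, 8),
               impute = round(runif(8, 0.5, 1), 3))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(gm, f)
  back <- read_genotypes(f, "vcf")
  expect_equal(back$samples, gm$samples)
  expect_equal(back$variants$snp_id, gm$variants$snp_id)
  expect_equal(back$dosages, gm$dosages, tolerance = 1e-6)
  expect_equal(back$variants$impute_score, gm$variants$impute_score,
               tolerance = 1e-5)
})

test_that("PLINK triple round-trips hard genotypes including missing", {
  set.seed(4)
  d <- matrix(sample(c(0, 1, 2, NA), 9 * 7, replace = TRUE), 9, 7)
  d[1, ] <- 2  # exercise all-codes paths
  gm <- toy_gm(d)
  prefix <- file.path(withr::local_tempdir(), "fx")
  write_genotypes_plink(gm, prefix)
  back <- read_genotypes(prefix, "plink")
  expect_equal(back$samples, gm$samples)
  expect_equal(back$variants$counted_allele, gm$variants$counted_allele)
  expect_equal(unname(back$dosages), unname(d))
})

test_that("QC removes variants at the thresholds strictly and is idempotent", {
  d <- matrix(1, 50, 3)
  d[1, 1] <- NA                                  # missingness 0.02 exactly
  gm <- toy_gm(d, impute = c(1, 0.8, 0.9))       # snp2 at 0.8 exactly
  kept <- suppressMessages(qc_filter_variants(gm))
  expect_equal(kept$variants$snp_id, "snp03")
  again <- qc_filter_variants(kept)
  expect_equal(again$variants, kept$variants)
  expect_equal(again$dosages, kept$dosages)

  clean <- toy_gm(matrix(1, 10, 4), impute = 1)
  expect_equal(qc_filter_variants(clean)$variants$snp_id,
               clean$variants$snp_id)
})

test_that("allele harmonisation flips, drops palindromes, recovers truth", {
  gm <- toy_gm(matrix(1, 4, 2), counted = c("G", "A"), other = c("A", "T"))
  ss <- toy_sumstats(c("snp01", "snp02"), pvalue = c(0.1, 0.2), beta = 0.5,
                     effect = c("A", "A"), other = c("G", "T"))
  h <- suppressMessages(harmonise_alleles(ss, gm))
  expect_equal(h$snp_id, "snp01")      # A/T palindrome dropped
  expect_equal(h$beta, -0.5)           # counted allele is the other allele

  # random fixture with known flips
  set.seed(9)
  m <- 100
  pair <- matrix(c("A", "A", "T", "T", "G", "C", "G", "C"), ncol = 2)
  pick <- sample(nrow(pair), m, replace = TRUE)
  true_beta <- rnorm(m)
  flipped <- runif(m) < 0.5
  ss <- toy_sumstats(sprintf("v%03d", 1:m), pvalue = runif(m))
  ss$beta <- true_beta
  ss$effect_allele <- pair[pick, 1]
  ss$other_allele <- pair[pick, 2]
  counted <- ifelse(flipped, ss$other_allele, ss$effect_allele)
  other <- ifelse(flipped, ss$effect_allele, ss$other_allele)
  gm <- toy_gm(matrix(1, 3, m))
  gm$variants$snp_id <- ss$snp_id
  gm$variants$counted_allele <- counted
  gm$variants$other_allele <- other
  colnames(gm$dosages) <- ss$snp_id
  h <- suppressMessages(harmonise_alleles(ss, gm))
  expect_equal(nrow(h), m)
  aligned_truth <- ifelse(flipped, -true_beta, true_beta)
  expect_equal(h$beta, aligned_truth[match(h$snp_id, ss$snp_id)])

  # harmonising the flipped encoding yields the identical aligned vector
  ss2 <- ss
  ss2$effect_allele <- ss$other_allele
  ss2$other_allele <- ss$effect_allele
  ss2$beta <- -ss$beta
  h2 <- suppressMessages(harmonise_alleles(ss2, gm))
  expect_equal(h2$beta, h$beta)
  expect_equal(h2$snp_id, h$snp_id)
})

test_that("phenotype, interaction, expression and config tables round-trip", {
  ph <- data.frame(sample_id = c("a", "b"), case_status = c(1L, 0L),
                   sex = c(1L, 0L), age = c(40.5, 39),
                   PC1 = c(0.1, -0.2), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(ph, f)
  expect_equal(read_phenotypes(f), ph)

  ex <- matrix(rnorm(6), 2, 3,
               dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  write_expression(ex, f)
  expect_equal(read_expression(f), ex)

  writeLines(c("sumstats: x.tsv", "alpha: 0.001"), f)
  cfg <- read_pes_config(f)
  expect_equal(cfg$alpha, 0.001)
})
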