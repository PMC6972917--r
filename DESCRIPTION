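Package: pescore
Title: Pharmagenic Enrichment Scores from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies druggable biological pathways enriched with
    trait-associated common variation from genome-wide association study
    (GWAS) summary statistics and computes pathway-restricted polygenic
    scores (pharmagenic enrichment scores, PES) for genotyped individuals.
    Provides gene-level P-value aggregation under linkage disequilibrium
    via Brown-style moment matching, competitive gene-set association,
    LD clumping and P-value thresholding, genome-wide polygenic risk
    scoring with Nagelkerke R-squared threshold optimisation, elevated-score
    percentile profiling, Gaussian mixture clustering with BIC model
    selection, drug-target over-representation analysis, and linear-model
    tests of score effects on gene expression. A synthetic-data module
    generates LD-block genotypes, liability-scale phenotypes, summary
    statistics, and expression matrices so that every stage can be
    exercised without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
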