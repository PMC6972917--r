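---
title: "Pathway-restricted polygenic scoring with pescore: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-restricted polygenic scoring with pescore: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pescore)
```

## Motivation

A genome-wide polygenic risk score (PRS) summarises an individual's
common-variant burden for a trait, but it is biologically anonymous: two
individuals with identical total scores may carry their risk in entirely
different biological systems. The pharmagenic enrichment score (PES)
framework partitions that burden over *druggable* pathways — gene sets
containing at least one high-confidence target of an approved drug — so
that an elevated score points at a system that an existing compound can
modulate. The package implements the full chain: trait-associated
pathway discovery from GWAS summary statistics, per-individual
pathway-restricted scoring, profiling of elevated-score carriers
against the genome-wide PRS, drug annotation of candidate pathways, and
linear-model tests of score effects on pathway gene expression. A
synthetic-data generator supplies every input with the statistical
structure the analysis assumes, so the pipeline is fully exercisable
without restricted cohort data.

## Gene-level omnibus statistic

SNPs are mapped to genes using windows of 5 kb upstream and 1.5 kb
downstream of the gene body on the strand-adjusted axis (the longer
upstream arm captures regulatory elements before the transcription
start site). Windows are closed intervals; genes overlapping the major
histocompatibility complex (default chr6:25–34 Mb, GRCh37 — the
interval is configurable since only the exclusion itself, not its
coordinates, is standard) are excluded because of the region's
haplotype complexity.

For a gene with $M$ SNP P values $P_1,\dots,P_M$, each P value is
transformed to a two-sided $\chi^2_1$ deviate
$q_j = \Phi^{-1}(1-P_j/2)^2$ and the gene statistic is the linear
combination $T=\sum_j q_j$. Under the null hypothesis the vector of
SNP Z scores is multivariate normal with correlation matrix $R$ (the
local LD matrix, estimated as the Pearson correlation of reference
dosages), so $T = z^\top z$ is a weighted sum of independent
$\chi^2_1$ variables with weights the eigenvalues of $R$. The gene P
value is the upper tail of this distribution at $T$, evaluated by
numerical characteristic-function inversion (Imhof's method) with an
adaptive tolerance ladder. Brown/Satterthwaite moment matching —
$E[T]=M$, $\mathrm{Var}[T]=2M+4\sum_{j<k}r_{jk}^2$, matched to a
scaled chi-square with scale $c=\mathrm{Var}/2E$ and
$\nu = 2E^2/\mathrm{Var}$ degrees of freedom — is reported alongside
as an interpretable summary of the null's spread, and serves as the
fallback tail if the quadrature fails. We initially used the
moment-matched tail as the P value itself, but its approximation error
(up to roughly 0.02 in the distribution's centre at strong LD) exceeds
what a Monte-Carlo cross-check at $10^5$ draws can absorb; the exact
inversion removes that error at negligible cost, while changing
nothing about the statistic being tested.

Two design points deserve note:

* **Perfect LD.** Variants that are perfectly correlated ($|r|=1$,
  e.g. a duplicated SNP) carry no independent information, yet summing
  their transforms would double-count both signal and null variance —
  and no tail correction makes the result exactly invariant to
  duplication. Each perfect-LD group is therefore collapsed to one
  effective SNP (the group's mean $q$) before the null is formed,
  which makes the gene P value exactly invariant to duplicating any
  variant.
* **Numerical guards.** Gene P values are clamped inside $(0,1)$ so
  the probit $Z=\Phi^{-1}(1-P)$ is finite, and $Z$ is clamped at
  $\pm 8.2$. Non-positive-semidefinite LD estimates (possible after
  mean imputation of sporadically missing dosages) are shrunk toward
  the identity, $(1-\lambda)R+\lambda I$ with $\lambda=0.001$, when
  the smallest eigenvalue falls below $10^{-8}$.

The analysis is repeated at a grid of P-value ceilings $P_T$ (default:
all SNPs, then 0.5, 0.05, 0.005) with strict inclusion
($P < P_T$), capturing components of the polygenic signal at varying
degrees of polygenicity.

## Competitive gene-set association

For each druggable pathway and each $P_T$, gene Z scores are regressed
on a set-membership indicator with an intercept and the gene's SNP
count and log SNP count as confounders, by ordinary least squares. The
reported P value is one-sided for a positive membership coefficient:
the alternative of interest is enrichment, not depletion. Candidate
pathways for scoring are those with $P < 0.001$ at one or more
ceilings; when a pathway is associated at several, the most significant
is chosen, with exact ties resolved toward the more stringent ceiling.

Inter-gene LD (adjacent genes sharing SNPs or haplotypes) is ignored by
the default OLS standard errors. At the simulated scale, genes occupy
disjoint LD blocks and the null calibration test confirms the 5% size;
on real, densely annotated genomes this assumption is optimistic and
set P values should be read as approximate.

## Scores

A score is the additive sum over its SNPs of the GWAS effect size
(beta scale; odds ratios are log-transformed on ingestion) times the
counted-allele dosage:
$\mathrm{PES}_i = \sum_j^M \hat\beta_j \, G_{ij}$.
The raw sum is the score; a per-SNP-count average is available behind
a flag for cross-cohort comparability but is off by default. Effect
alleles are harmonised to the genotype file's counted allele by
(chromosome, position, allele-pair) join, sign-flipping where the
counted allele is the non-effect allele and dropping strand-ambiguous
palindromic pairs (A/T, C/G) — a declared policy, as the harmonisation
protocol of any individual study is rarely printed. Missing dosages
are mean-imputed per variant so every individual's score sums over the
same SNPs.

SNPs entering any score are first LD-clumped: greedy iteration by
ascending P (ties by lexicographic SNP id, for determinism), retaining
each index SNP and removing unretained SNPs within 250 kb at
$r^2 > 0.1$ — conventional PRS defaults, since clumping parameters are
a tooling convention rather than a finding. Pathway scores restrict to
SNPs mapped to the pathway's genes at the pathway's selected $P_T$;
the genome-wide PRS is clumped once and then thresholded along a
ceiling grid (default $5\times10^{-8}$ to 1), choosing the ceiling
that maximises the increment of Nagelkerke's $R^2$ —
$R^2 = [1-\exp(\frac{2}{n}(L_0-L_1))]/[1-\exp(\frac{2}{n}L_0)]$ —
of `case ~ score + covariates` over the covariates-only model. The
genome-wide PRS keeps the MHC (exclusion there is specific to the
gene-level analysis); pathway scores inherit the exclusion through the
gene map.

## Profiling elevated scores

Percentile flags use the nearest-rank rule: at level $q$ over $N$
individuals, the top $\lceil (1-q)N \rceil$ score-holders are flagged,
with boundary ties all included. Ranking is computed in the pooled
case-control cohort by default (a `subset` argument restricts it).
Per-individual counts of elevated pathways at the 75th/90th/99th levels
are nested by construction. Association of scores or counts with case
status uses binomial logistic regression adjusted for sex and the
leading principal components, with Wald inference
($z=\hat\beta/SE$, $CI_{95} = \exp(\hat\beta \pm 1.96\,SE)$), run with
and without the genome-wide PRS as an additional covariate to separate
pathway-specific from total polygenic signal.

The joint structure of (genome-wide PRS, elevated-pathway count) is
clustered by finite Gaussian mixtures fitted with in-package EM over
six covariance families — spherical/diagonal/full crossed with
equal/variable across components (EII, VII, EEI, VVI, EEE, VVV in
mclust nomenclature). Initialisation is seeded k-means with 10
restarts; convergence at relative log-likelihood change $10^{-6}$,
at most 500 iterations; a covariance floor of $10^{-6}$ times the
mean marginal variance guards spiked components, and a candidate whose
covariance still sits on the floor at convergence is discarded as
degenerate rather than allowed to win on an inflated likelihood.
Model selection maximises $BIC = 2\ell - k\log n$ (the mixture-model
sign convention). Orientation-constrained ellipsoidal families (such
as VEV) are not implemented; at two dimensions the six families cover
the geometry the clustering needs, and the full-covariance families
subsume orientation freedom per component. Cluster over-representation
of top-percentile carriers is tested by multinomial logistic
regression against the largest cluster as reference, with Wald P per
contrast; clusters under 5 members are dropped.

## Drug annotation and expression

Drug-target over-representation per candidate pathway uses the
hypergeometric upper tail $P(X \ge k)$ with the annotation file's gene
universe, Benjamini-Hochberg correction across the drugs tested for
that pathway (every drug with at least one target in the universe —
the correction is per pathway, mirroring the per-pathway reporting),
and two gates: $q < 0.05$ and target overlap $\ge 3$. Top-drug
selection offers two modes: highest interaction-confidence score among
approved drugs hitting a druggable pathway gene, or smallest ORA
q-value with ties to the larger overlap and then lexicographic drug
name.

Expression effects are tested per (pathway, gene available in the
expression matrix) by OLS of expression on the pathway score with age,
sex and the genome-wide PRS as covariates, reporting $t=\hat\beta/SE$
and a BH q-value computed within the pathway, flagged at the
exploratory cut-off $q<0.1$. Genes in several candidate pathways are
tested once per pathway, matching the per-pathway correction
structure. Expression is assumed pre-normalised.

## The synthetic study

The generator emulates the statistical structure the analysis assumes,
not human genomic realism:

* **Genotypes**: latent-Gaussian haplotype pairs thresholded at the
  allele-frequency quantile, AR(1) correlation within LD blocks,
  blocks independent. This gives controllable LD at desk-scale speed;
  coalescent realism, population structure and ascertainment are
  non-goals.
* **Genome layout**: 4 kb genes every 20 kb on one chromosome, SNPs
  spread evenly in gene bodies, so each SNP maps to exactly one gene
  and mapping oracles are exact.
* **Phenotype**: additive liability threshold model. SNPs in planted
  "enriched" pathways are causal with effect variance multiplied by a
  configurable factor (default 25) over unit-variance background
  effects (background causal fraction 0.2); the genetic score is
  rescaled to heritability $h^2$ and cases exceed the
  $1-K$ liability quantile.
* **GWAS**: per-SNP logistic regression on the simulated cohort. By
  default the same cohort is emitted for scoring; a two-cohort mode
  runs the GWAS on a separate discovery sample, the structure of a
  consortium GWAS applied to an independent target cohort, and the one
  used wherever a test would otherwise couple effect estimation to
  scoring through winner's curse.
* **Expression**: linear in the standardised pathway score for a
  designated subset of pathway genes (default slope 0.8 per score SD
  against unit noise — a large, comfortably detectable effect at
  n = 75), plus a weak age trend.

The `paper_shaped` preset mirrors the shape of a realistic
schizophrenia case-control application: a 425-case/251-control target
cohort (prevalence overridden to 0.35 at desk scale so the quota is
reachable from a modest pool; the population default is 0.7%), 2000
SNPs in 250 genes, 50 druggable pathways of 8 genes with eight planted
candidates, a 4000-strong discovery GWAS (two-cohort mode), and a
75-case expression subset. Effect sizes were fixed by a power
calculation, not by tuning: with 4000 discovery samples and variance
multiplier 25, an enriched SNP carries roughly $4\times10^{-3}$ of
liability variance, giving expected per-SNP association
$\chi^2 \approx 4$–5, gene Z around 2–2.5, and a one-sided competitive
t of 5 or more for a planted set of 8 such genes — comfortably below
the 0.001 selection threshold, while background pathways stay null.
With a single planted pathway the same multiplier concentrates ~80% of
$h^2$ in 64 SNPs and recovery is near-certain.

Everything is deterministic given the seed: child generators derive
their streams from the master seed with fixed offsets, so each stage
is individually reproducible. The causal architecture (which SNPs are
causal and their true effects) is drawn from a stream fixed by the
configuration alone, so every cohort simulated from one configuration
shares the same genetic truth — the property that lets a discovery
GWAS transfer to an independent target cohort — while genotypes,
liability noise and covariates use per-cohort streams and are
independent between cohorts.

## What the tests do and do not show

The simulated data have disjoint LD blocks, no population
stratification (principal components are pure noise), exact SNP-gene
assignment, no genotyping error beyond what QC filters see, and
planted effects far stronger per SNP than typical common-variant
architecture. Passing tests therefore demonstrate the correctness of
the machinery — exact score arithmetic, calibrated null distributions,
faithful recovery of planted structure — not the field performance of
the method on real cohorts, where LD leakage between genes, subtle
stratification and weaker effects all matter. Problem sizes in the
test suite (e.g. 20 recovery runs at the paper-shaped scale, $10^5$
Monte-Carlo null draws per gene fixture, 2000 null replicates of the
competitive test) were chosen to keep the full suite in the
tens-of-minutes range on a single core.

## Known limitations

* Set-level standard errors ignore inter-gene correlation (an optional
  robustness mode is noted in the design but real-genome use should
  treat set P values as approximate).
* The score does not integrate direction of effect: an elevated PES
  flags burden in a pathway, not whether a drug should agonise or
  antagonise it.
* PLINK input is read as hard calls (bed format has no dosage field);
  fractional dosages require the VCF `DS` route.
* The drug interaction table is consumed as given; no live database
  queries or ATC ontology expansion.
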