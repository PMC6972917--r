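# Shared fixture builders; everything is generated in code at test time.

# small hand-rolled genotype matrix with explicit dosages
toy_gm <- function(dosages, chrom = "1", pos = NULL, counted = "A",
                   other = "G", impute = NA_real_) {
  m <- ncol(dosages)
  pos <- pos %||% seq(1000, by = 1000, length.out = m)
  variants <- data.frame(
    snp_id = sprintf("snp%02d", seq_len(m)), chrom = chrom, pos = pos,
    counted_allele = counted, other_allele = other,
    impute_score = impute, stringsAsFactors = FALSE
  )
  genotype_matrix(sprintf("ind%02d", seq_len(nrow(dosages))), variants,
                  dosages)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# summary stats frame from parallel vectors
toy_sumstats <- function(snp_id, pvalue, beta = 0, chrom = "1",
                         pos = NULL, effect = "A", other = "G") {
  n <- length(snp_id)
  data.frame(snp_id = snp_id, chrom = rep_len(chrom, n),
             pos = pos %||% seq(1000, by = 1000, length.out = n),
             effect_allele = rep_len(effect, n),
             other_allele = rep_len(other, n),
             beta = rep_len(beta, n), pvalue = pvalue,
             stringsAsFactors = FALSE)
}

# independent step-up BH used as the oracle against bh_adjust():
# q_(i) = min_{j >= i} m/j * P_(j), clipped at 1
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- m / seq_len(m) * p[o]
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# hypergeometric upper tail by exhaustive enumeration over all draws
hyper_tail_oracle <- function(k, N, K, n) {
  ks <- 0:min(K, n)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= k])
}
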