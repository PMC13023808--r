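# Shared fixtures and independent oracles, all built in code.

# Hand-build a harmonized set without going through harmonize(), so estimator
# tests are independent of the harmonization code path.
mk_hset <- function(beta_exp, se_exp, beta_out, se_out,
                    n_exp = 30000, n_out = 700000, snp_id = NULL) {
  j <- length(beta_exp)
  h <- data.frame(
    snp_id = snp_id %||% paste0("rs", seq_len(j)), chrom = "1",
    pos = seq_len(j) * 1e5, effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = rep_len(se_exp, j), pval_exp = 1e-10,
    eaf = 0.3, beta_out = beta_out, se_out = rep_len(se_out, j),
    pval_out = 0.5, eaf_out = 0.3, stringsAsFactors = FALSE
  )
  structure(h, class = c("harmonized_set", "data.frame"),
            exposure_id = "E", outcome_id = "O",
            outcome_type = "quantitative", n_exp = n_exp, n_out = n_out,
            drop_log = mrchain:::empty_drop_log())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Quick gwas_table from loose vectors.
mk_table <- function(snp_id, pval, beta = 0.1, se = 0.01, chrom = "1",
                     pos = seq_along(snp_id) * 1e5, ea = "A", oa = "G",
                     eaf = 0.3, n = 10000, trait_id = "trait",
                     trait_type = "quantitative", n_cases = NULL) {
  gwas_table(data.frame(
    snp_id = snp_id, chrom = chrom, pos = pos, effect_allele = ea,
    other_allele = oa, eaf = eaf, beta = rep_len(beta, length(snp_id)),
    se = rep_len(se, length(snp_id)), pval = rep_len(pval, length(snp_id)),
    n = n, stringsAsFactors = FALSE
  ), trait_id = trait_id, trait_type = trait_type, n_cases = n_cases)
}

# Restrict a gwas_table to chosen SNPs (rebuilding validation from scratch).
subset_table <- function(tab, ids) {
  gwas_table(as.data.frame(tab)[tab$snp_id %in% ids, ],
             trait_id = attr(tab, "trait_id"),
             trait_type = attr(tab, "trait_type"),
             n_cases = if (all(is.na(tab$n_cases))) NULL else tab$n_cases[1])
}

# Independent weighted-median interpolation oracle: explicit loop, no approx().
wm_oracle <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]; w <- w[ord]
  s <- cumsum(w)
  p <- (s - w / 2) / sum(w)
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(r)])
  k <- which(p >= 0.5)[1]
  r[k - 1] + (r[k] - r[k - 1]) * (0.5 - p[k - 1]) / (p[k] - p[k - 1])
}

# Independent greedy clumping oracle over explicit index loops.
clump_oracle <- function(pval, chrom, pos, r2, r2_max, window_kb) {
  remaining <- seq_along(pval)
  kept <- integer(0)
  while (length(remaining) > 0) {
    i <- remaining[which.min(pval[remaining])]
    kept <- c(kept, i)
    remaining <- setdiff(remaining, i)
    linked <- remaining[chrom[remaining] == chrom[i] &
                          abs(pos[remaining] - pos[i]) <= window_kb * 1000 &
                          r2[i, remaining] >= r2_max]
    remaining <- setdiff(remaining, linked)
  }
  sort(kept)
}

# Random valid LD matrix of squared correlations.
random_ld <- function(ids) {
  k <- length(ids)
  m <- matrix(stats::rnorm(k * k), k)
  r2 <- stats::cov2cor(crossprod(m))^2
  ld_matrix(r2, ids)
}

mk_mr_result <- function(beta, se, exposure = NA, outcome = NA, method = "ivw") {
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                 pval = 2 * stats::pnorm(-abs(beta / se)), n_snp = 5L,
                 exposure = exposure, outcome = outcome, extras = list()),
            class = "mr_result")
}
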