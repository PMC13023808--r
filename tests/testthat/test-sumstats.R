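# Instrument QC: table validation, IO dialects, selection, clumping,
# F filtering, harmonization, Steiger filtering.

test_that("gwas_table validates records, logs drops, keeps smallest-p duplicate", {
  df <- data.frame(
    snp_id = c("rs1", "rs2", "rs3", "rs3", "rs4", "rs5"),
    chrom = "1", pos = 1:6 * 1e5,
    effect_allele = c("A", "A", "G", "G", "A", "A"),
    other_allele = c("G", "A", "T", "T", "C", "C"),
    eaf = c(0.3, 0.3, 0.3, 0.3, 1.2, 0.3),
    beta = 0.1, se = c(0.01, 0.01, 0.01, 0.01, 0.01, 0),
    pval = c(1e-8, 1e-8, 1e-4, 1e-6, 1e-8, 1e-8), n = 1000
  )
  tab <- gwas_table(df, "t")
  expect_s3_class(tab, "gwas_table")
  expect_identical(tab$snp_id, c("rs1", "rs3"))      # rs3: smaller-p copy kept
  expect_equal(tab$pval[tab$snp_id == "rs3"], 1e-6)
  log <- attr(tab, "drop_log")
  expect_setequal(log$reason[log$snp_id == "rs2"], "same_alleles")
  expect_setequal(log$reason[log$snp_id == "rs4"], "invalid_eaf")
  expect_setequal(log$reason[log$snp_id == "rs5"], "nonpositive_se")
  expect_true("duplicate_snp_id" %in% log$reason[log$snp_id == "rs3"])

  # 3 well-formed rows pass through unchanged
  ok <- gwas_table(df[df$snp_id %in% c("rs1", "rs3"), ][1:2, ], "t2")
  expect_equal(nrow(ok), 2)
  expect_error(gwas_table(df[, setdiff(names(df), "se")], "t"), "mandatory")
  expect_error(gwas_table(transform(df, se = 0), "t"), "no records survive")
})

test_that("read_gwas_table maps dialects onto the canonical layout", {
  canon <- file.path(tempdir(), "canon.tsv")
  alt <- file.path(tempdir(), "alt.tsv")
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = "2", POS = 1:3 * 1e4,
                   EA = "A", OA = "G", EAF = 0.25, BETA = c(0.1, -0.2, 0.05),
                   SE = 0.02, P = c(1e-9, 1e-7, 0.2), N = 5000)
  write.table(df, canon, sep = "\t", quote = FALSE, row.names = FALSE)
  names(df) <- c("rsid", "chromosome", "bp", "a1", "a2", "freq", "b", "se", "p", "n")
  write.table(df, alt, sep = "\t", quote = FALSE, row.names = FALSE)

  t1 <- read_gwas_table(canon, trait_id = "x")
  t2 <- read_gwas_table(alt, trait_id = "x",
                        dialect = c(rsid = "SNP", chromosome = "CHR", bp = "POS",
                                    a1 = "effect_allele", a2 = "other_allele",
                                    freq = "EAF", b = "BETA"))
  expect_equal(as.data.frame(t1), as.data.frame(t2), ignore_attr = TRUE)
  expect_error(read_gwas_table(alt, trait_id = "x"), "dialect")
})

test_that("instrument selection is strict and idempotent", {
  tab <- mk_table(c("a", "b", "c"), pval = c(1e-9, 4e-6, 6e-6))
  sel <- select_instruments(tab, 5e-6)
  expect_identical(sel$snp_id, c("a", "b"))
  # exact threshold ties are excluded (strict inequality)
  tie <- mk_table(c("a", "b"), pval = c(5e-6, 1e-9))
  expect_identical(select_instruments(tie, 5e-6)$snp_id, "b")
  # all below a harsher threshold are retained
  strong <- mk_table(c("a", "b"), pval = 1e-9)
  expect_equal(nrow(select_instruments(strong, 5e-8)), 2)
  expect_identical(as.data.frame(select_instruments(sel, 5e-6))[, 1:11],
                   as.data.frame(sel)[, 1:11])
  expect_warning(select_instruments(mk_table("a", pval = 0.5), 5e-8),
                 "no SNP")
  expect_error(select_instruments(tab, 0), "p_threshold")
})

test_that("greedy clumping keeps the worked 3-SNP solution and respects the window", {
  tab <- mk_table(c("s1", "s2", "s3"), pval = c(1e-10, 1e-9, 1e-8),
                  pos = c(1e6, 2e6, 3e6))
  r2 <- diag(3); r2[1, 2] <- r2[2, 1] <- 0.5
  ld <- ld_matrix(r2, c("s1", "s2", "s3"))
  out <- clump(tab, ld, r2_max = 0.001, window_kb = 10000)
  expect_identical(out$snp_id, c("s1", "s3"))
  expect_true("ld_with_index_snp" %in% attr(out, "drop_log")$reason)

  # independent pairs are all retained
  expect_equal(nrow(clump(tab, ld_matrix(diag(3), tab$snp_id), 0.001, 10000)), 3)
  # linked pair outside the window is retained
  far <- mk_table(c("s1", "s2"), pval = c(1e-10, 1e-9), pos = c(1e6, 2.1e7))
  ld2 <- ld_matrix(matrix(c(1, .5, .5, 1), 2), c("s1", "s2"))
  expect_equal(nrow(clump(far, ld2, r2_max = 0.001, window_kb = 10000)), 2)
  expect_error(clump(tab, ld, r2_max = 0, window_kb = 10000), "r2_max")
  expect_error(clump(tab, ld, r2_max = 0.1, window_kb = -1), "window_kb")
})

test_that("clump matches an independent greedy oracle and returns independent sets", {
  set.seed(41)
  for (rep in 1:10) {
    j <- sample(5:12, 1)
    ids <- paste0("v", seq_len(j))
    tab <- mk_table(ids, pval = runif(j, 1e-12, 1e-4),
                    chrom = sample(c("1", "2"), j, replace = TRUE),
                    pos = sample(1e6:2e7, j))
    ld <- random_ld(ids)
    r2_max <- runif(1, 0.05, 0.6)
    out <- clump(tab, ld, r2_max = r2_max, window_kb = 10000)
    oracle <- sort(match(clump_oracle(tab$pval, tab$chrom, tab$pos,
                                      unclass(ld), r2_max, 10000), seq_len(j)))
    expect_identical(sort(match(out$snp_id, ids)), oracle)
    # no retained pair within the window violates the threshold
    for (a in seq_len(nrow(out))) for (b in seq_len(nrow(out))) {
      if (a < b && out$chrom[a] == out$chrom[b] &&
          abs(out$pos[a] - out$pos[b]) <= 1e7) {
        expect_lt(ld[out$snp_id[a], out$snp_id[b]], r2_max)
      }
    }
  }
})

test_that("SNPs absent from the LD matrix are treated as unlinked with a warning", {
  tab <- mk_table(c("s1", "s2"), pval = c(1e-10, 1e-9), pos = c(1e6, 1.1e6))
  ld <- ld_matrix(matrix(1), "s1")
  expect_warning(out <- clump(tab, ld, 0.001, 10000), "unlinked")
  expect_equal(nrow(out), 2)
})

test_that("F statistic is (beta/se)^2, sign-invariant, and filters weak instruments", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(0.1, 0.05), 4)
  expect_equal(f_statistic(0, 0.01), 0)
  z <- rnorm(20)
  expect_equal(f_statistic(z, 0.3), f_statistic(-z, 0.3))
  tab <- mk_table(c("strong", "weak", "zero"), pval = 1e-9,
                  beta = c(0.1, 0.1, 0), se = c(0.02, 0.05, 0.01))
  out <- filter_weak_instruments(tab, f_min = 10)
  expect_identical(out$snp_id, "strong")
  log <- attr(out, "drop_log")
  expect_setequal(log$snp_id[log$reason == "weak_instrument"], c("weak", "zero"))
  expect_error(f_statistic(0.1, 0), "se")
})

make_pair_tables <- function(out_ea = "G", out_oa = "A", out_beta = 0.1,
                             out_eaf = 0.3, exp_ea = "A", exp_oa = "G",
                             exp_eaf = 0.3) {
  exp <- mk_table("rs1", pval = 1e-9, ea = exp_ea, oa = exp_oa, eaf = exp_eaf,
                  trait_id = "exp")
  out <- mk_table("rs1", pval = 0.01, beta = out_beta, ea = out_ea, oa = out_oa,
                  eaf = out_eaf, trait_id = "out")
  list(exp = exp, out = out)
}

test_that("harmonization aligns, flips, complements, and drops as documented", {
  # swapped alleles: sign and frequency flip
  tt <- make_pair_tables(out_ea = "G", out_oa = "A")
  h <- harmonize(tt$exp, tt$out)
  expect_equal(h$beta_out, -0.1)
  expect_equal(h$eaf_out, 0.7)
  # identical orientation: unchanged
  tt <- make_pair_tables(out_ea = "A", out_oa = "G")
  h <- harmonize(tt$exp, tt$out)
  expect_equal(h$beta_out, 0.1)
  expect_equal(h$eaf_out, 0.3)
  # strand complement, same orientation (A/G vs T/C): copy
  tt <- make_pair_tables(out_ea = "T", out_oa = "C")
  expect_equal(harmonize(tt$exp, tt$out)$beta_out, 0.1)
  # strand complement, swapped (A/G vs C/T): flip
  tt <- make_pair_tables(out_ea = "C", out_oa = "T")
  expect_equal(harmonize(tt$exp, tt$out)$beta_out, -0.1)
  # incompatible pairs dropped
  exp2 <- mk_table(c("rs1", "rs2"), pval = 1e-9, ea = "A", oa = "G", trait_id = "e")
  out2 <- mk_table(c("rs1", "rs2"), pval = 0.01, ea = c("A", "A"),
                   oa = c("G", "T"), trait_id = "o")
  h <- harmonize(exp2, out2)
  expect_identical(h$snp_id, "rs1")
  log <- attr(h, "drop_log")
  expect_true(any(log$snp_id == "rs2" & log$reason == "incompatible_alleles"))
  expect_error(harmonize(mk_table("rsA", 1e-9), mk_table("rsB", 0.1)),
               "no shared SNPs")
})

test_that("palindromic SNPs resolve by frequency or drop as ambiguous", {
  # eaf 0.50 in the ambiguity band: dropped
  tt <- make_pair_tables(exp_ea = "A", exp_oa = "T", out_ea = "A", out_oa = "T",
                         exp_eaf = 0.5, out_eaf = 0.5)
  expect_error(h <- harmonize(tt$exp, tt$out, palindrome_eaf_band = 0.08),
               "no SNPs survive")
  # informative frequencies on the same side: copied
  tt <- make_pair_tables(exp_ea = "A", exp_oa = "T", out_ea = "A", out_oa = "T",
                         exp_eaf = 0.2, out_eaf = 0.25)
  expect_equal(harmonize(tt$exp, tt$out)$beta_out, 0.1)
  # opposite sides of 1/2: flipped
  tt <- make_pair_tables(exp_ea = "A", exp_oa = "T", out_ea = "A", out_oa = "T",
                         exp_eaf = 0.2, out_eaf = 0.8)
  h <- harmonize(tt$exp, tt$out)
  expect_equal(h$beta_out, -0.1)
  # the reason code is logged when other SNPs survive
  exp2 <- mk_table(c("p1", "k1"), pval = 1e-9, ea = c("A", "A"),
                   oa = c("T", "G"), eaf = 0.5, trait_id = "e")
  out2 <- mk_table(c("p1", "k1"), pval = 0.01, ea = c("A", "A"),
                   oa = c("T", "G"), eaf = 0.5, trait_id = "o")
  h <- harmonize(exp2, out2)
  expect_identical(h$snp_id, "k1")
  log <- attr(h, "drop_log")
  expect_true(any(log$snp_id == "p1" & log$reason == "ambiguous_palindrome"))
})

test_that("harmonization is idempotent and invariant to whole-table allele flips", {
  set.seed(7)
  s <- simulate_chain(chain_sim_config(j_exp = 8, j_med = 4, seed = 13))
  h1 <- harmonize(s$exposure_gwas, s$outcome_gwas)

  # rebuilding the outcome from the harmonized set and re-harmonizing is a no-op
  out_df <- as.data.frame(s$outcome_gwas)
  idx <- match(h1$snp_id, out_df$snp_id)
  out2_df <- out_df[idx, ]
  out2_df$effect_allele <- h1$effect_allele
  out2_df$other_allele <- h1$other_allele
  out2_df$beta <- h1$beta_out
  out2_df$eaf <- h1$eaf_out
  out2 <- gwas_table(out2_df, "outcome", "binary", n_cases = 8434)
  h2 <- harmonize(s$exposure_gwas, out2)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$eaf_out, h1$eaf_out)

  # flipping every outcome record (swap alleles, negate beta, 1 - eaf) is
  # undone by harmonization
  flip_df <- out_df
  flip_df$effect_allele <- out_df$other_allele
  flip_df$other_allele <- out_df$effect_allele
  flip_df$beta <- -out_df$beta
  flip_df$eaf <- 1 - out_df$eaf
  out3 <- gwas_table(flip_df, "outcome", "binary", n_cases = 8434)
  h3 <- harmonize(s$exposure_gwas, out3)
  expect_equal(h3$beta_out, h1$beta_out, tolerance = 1e-12)
  expect_equal(h3$snp_id, h1$snp_id)
})

test_that("Steiger filtering removes instruments explaining more outcome variance", {
  # hand arithmetic: r2 = Z^2 / (Z^2 + n)
  h <- mk_hset(beta_exp = 0.1, se_exp = 0.01, beta_out = 0.002, se_out = 0.001,
               n_exp = 30000, n_out = 700000)
  res <- steiger_filter(h)
  expect_equal(res$report$r2_exp, 100 / 30100, tolerance = 1e-12)
  expect_equal(res$report$r2_out, 4 / 700004, tolerance = 1e-12)
  expect_equal(nrow(res$hset), 1)

  # reverse-direction SNP dropped, correctly oriented SNP kept
  h2 <- mk_hset(beta_exp = c(0.1, 0.002), se_exp = c(0.01, 0.001),
                beta_out = c(0.002, 0.1), se_out = c(0.001, 0.01),
                n_exp = 30000, n_out = 30000)
  res2 <- steiger_filter(h2)
  expect_identical(res2$hset$snp_id, "rs1")
  log <- attr(res2$hset, "drop_log")
  expect_true(any(log$reason == "steiger_reverse" & log$snp_id == "rs2"))
  expect_false(res2$report$direction_ok[2])
  expect_true(all(res2$report$steiger_p >= 0 & res2$report$steiger_p <= 1))

  # all-correct set passes through untouched
  h3 <- mk_hset(beta_exp = c(0.2, 0.3), se_exp = 0.01,
                beta_out = c(0.01, 0.02), se_out = 0.01)
  expect_equal(as.data.frame(steiger_filter(h3)$hset), as.data.frame(h3))
  h_bad <- mk_hset(0.1, 0.01, 0.01, 0.01, n_exp = 2, n_out = 100)
  expect_error(steiger_filter(h_bad), "sample sizes")
})

test_that("LD matrix readers accept square and long formats and validate shape", {
  sq <- file.path(tempdir(), "ld_sq.tsv")
  lg <- file.path(tempdir(), "ld_long.tsv")
  m <- matrix(c(1, .4, 0, .4, 1, .2, 0, .2, 1), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  write.table(as.data.frame(m), sq, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(snp_a = c("a", "b", "a"), snp_b = c("b", "c", "c"),
                         r2 = c(.4, .2, 0)), lg, sep = "\t", quote = FALSE,
              row.names = FALSE)
  m1 <- read_ld_matrix(sq)
  m2 <- read_ld_matrix(lg)
  expect_equal(unclass(m1)[c("a", "b", "c"), c("a", "b", "c")],
               unclass(m2)[c("a", "b", "c"), c("a", "b", "c")])
  bad <- m; bad[1, 2] <- 0.9
  expect_error(ld_matrix(bad, rownames(bad)), "symmetric")
  expect_error(ld_matrix(m - diag(3) * 0.5, rownames(m)), "diagonal")
})
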