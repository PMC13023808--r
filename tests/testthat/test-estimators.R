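# The five estimators against hand arithmetic, closed forms, and independent
# weighted-least-squares / brute-force oracles.

test_that("Wald ratio matches first-order delta arithmetic", {
  r <- wald_ratio(0.1, 0.01, 0.02, 0.005)
  expect_equal(r$beta, 0.2)
  expect_equal(r$se, 0.05)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.005)$beta, 0)
  # joint negation (allele recoding) leaves the estimate unchanged
  expect_equal(wald_ratio(-0.1, 0.01, -0.02, 0.005)$beta, r$beta)
  expect_equal(wald_ratio(-0.1, 0.01, -0.02, 0.005)$se, r$se)
  expect_error(wald_ratio(0, 0.01, 0.02, 0.005), "nonzero")
})

worked_hset <- function() {
  mk_hset(beta_exp = c(0.1, 0.2, 0.15), se_exp = 0.01,
          beta_out = c(0.02, 0.05, 0.03), se_out = 0.005)
}

test_that("IVW reproduces the worked 3-SNP example and its degenerate cases", {
  r <- mr_ivw(worked_hset())
  expect_equal(r$beta, 660 / 2900, tolerance = 1e-10)   # 0.22759
  expect_equal(r$extras$q, 1.7931034, tolerance = 1e-6)
  # Q/(J-1) < 1: no random-effects inflation
  expect_equal(r$se, r$extras$se_fixed)
  expect_true(r$ci_low <= r$beta && r$beta <= r$ci_high)

  # all per-SNP ratios equal 0.25: beta = 0.25, Q = 0
  h <- mk_hset(beta_exp = c(0.1, 0.2, 0.4), se_exp = 0.01,
               beta_out = c(0.025, 0.05, 0.1), se_out = 0.005)
  r0 <- mr_ivw(h)
  expect_equal(r0$beta, 0.25)
  expect_equal(r0$extras$q, 0, tolerance = 1e-20)

  # single instrument delegates to the Wald ratio
  h1 <- mk_hset(0.1, 0.01, 0.02, 0.005)
  r1 <- mr_ivw(h1)
  w1 <- wald_ratio(0.1, 0.01, 0.02, 0.005)
  expect_equal(r1$beta, w1$beta)
  expect_equal(r1$se, w1$se)
})

test_that("MR-Egger recovers an exact linear fit and refuses tiny sets", {
  h <- mk_hset(beta_exp = c(0.1, 0.2, 0.3), se_exp = 0.01,
               beta_out = c(0.05, 0.07, 0.09), se_out = 0.01)
  r <- mr_egger(h)
  expect_equal(r$beta, 0.2, tolerance = 1e-10)
  expect_equal(r$extras$intercept, 0.03, tolerance = 1e-10)
  expect_equal(r$extras$q, 0, tolerance = 1e-18)

  h0 <- mk_hset(beta_exp = c(0.1, 0.2, 0.3), se_exp = 0.01,
                beta_out = c(0, 0, 0), se_out = 0.01)
  r0 <- mr_egger(h0)
  expect_equal(r0$beta, 0)
  expect_equal(r0$extras$intercept, 0)
  expect_error(mr_egger(mk_hset(c(0.1, 0.2), 0.01, c(0.01, 0.02), 0.01)),
               "at least 3")
})

test_that("IVW and Egger match the generic weighted-least-squares oracle", {
  set.seed(31)
  for (rep in 1:25) {
    j <- sample(3:12, 1)
    h <- simulate_instruments(j, beta = runif(1, -0.5, 0.5),
                              se_y = runif(j, 0.01, 0.1))
    w <- 1 / h$se_out^2
    fit0 <- lm(beta_out ~ 0 + beta_exp, data = h, weights = w)
    r <- mr_ivw(h)
    expect_equal(r$beta, unname(coef(fit0)), tolerance = 1e-10)
    expect_equal(r$extras$q, sum(w * resid(fit0)^2), tolerance = 1e-10)
    oriented <- transform(as.data.frame(h),
                          beta_out = beta_out * sign(beta_exp),
                          beta_exp = abs(beta_exp))
    fit1 <- lm(beta_out ~ beta_exp, data = oriented, weights = w)
    e <- mr_egger(h)
    expect_equal(e$beta, unname(coef(fit1)[2]), tolerance = 1e-10)
    expect_equal(e$extras$intercept, unname(coef(fit1)[1]), tolerance = 1e-10)
    # SE equals the WLS fixed SE times the capped inflation factor
    infl <- max(1, sqrt(sum(w * resid(fit1)^2) / (j - 2)))
    se_fixed <- unname(sqrt(diag(vcov(fit1)))[2]) / summary(fit1)$sigma
    expect_equal(e$se, se_fixed * infl, tolerance = 1e-8)
  }
})

test_that("weighted median interpolates the weighted ratio quantile", {
  # equal weights: cumulative weight hits 0.5 exactly at the middle ratio
  h <- mk_hset(beta_exp = c(1, 1, 1), se_exp = 0.01,
               beta_out = c(0.1, 0.2, 0.3), se_out = 0.01)
  expect_equal(mr_weighted_median(h, n_boot = 200, seed = 1)$beta, 0.2)
  # weights (1, 1, 2) on ratios (0.1, 0.2, 0.3) interpolate to 0.2333
  hw <- mk_hset(beta_exp = c(1, 1, sqrt(2)), se_exp = 0.01,
                beta_out = c(0.1, 0.2, 0.3 * sqrt(2)), se_out = 0.01)
  expect_equal(mr_weighted_median(hw, n_boot = 200, seed = 1)$beta, 0.7 / 3,
               tolerance = 1e-10)
  # identical ratios collapse to that ratio with vanishing bootstrap spread
  hc <- mk_hset(beta_exp = c(0.1, 0.2, 0.3), se_exp = 1e-8,
                beta_out = 0.25 * c(0.1, 0.2, 0.3), se_out = 1e-8)
  rc <- mr_weighted_median(hc, n_boot = 200, seed = 2)
  expect_equal(rc$beta, 0.25, tolerance = 1e-6)
  expect_lt(rc$se, 1e-6)
  expect_warning(mr_weighted_median(h, n_boot = 50, seed = 1), "n_boot")
})

test_that("weighted median equals the brute-force interpolation oracle (J <= 6)", {
  set.seed(32)
  for (rep in 1:40) {
    j <- sample(3:6, 1)
    h <- simulate_instruments(j, beta = runif(1, -1, 1),
                              se_y = runif(j, 0.01, 0.2))
    est <- mr_weighted_median(h, n_boot = 100, seed = rep)$beta
    ratio <- h$beta_out / h$beta_exp
    w <- h$beta_exp^2 / h$se_out^2
    expect_equal(est, wm_oracle(ratio, w), tolerance = 1e-12)
    expect_gte(est, min(ratio))
    expect_lte(est, max(ratio))
  }
})

test_that("mode estimators find the ratio cluster and honor the bandwidth rule", {
  h <- mk_hset(beta_exp = rep(1, 4), se_exp = 0.01,
               beta_out = c(0.2, 0.2, 0.2, 0.9), se_out = 0.01)
  r <- mr_mode(h, weighted = FALSE, n_boot = 200, seed = 1)
  expect_equal(r$beta, 0.2, tolerance = 0.05)
  expect_equal(r$extras$phi, 1)
  expect_gt(r$extras$bandwidth, 0)
  # brute-force density check on the returned grid position
  ratio <- h$beta_out / h$beta_exp
  dens <- function(g) sum(dnorm(g - ratio, sd = r$extras$bandwidth))
  expect_gte(dens(r$beta), dens(0.9))

  # all ratios identical: that ratio, zero bandwidth path
  hc <- mk_hset(beta_exp = c(1, 2, 4), se_exp = 0.01,
                beta_out = 0.3 * c(1, 2, 4), se_out = 0.01)
  rc <- mr_mode(hc, n_boot = 200, seed = 1)
  expect_equal(rc$beta, 0.3, tolerance = 1e-10)

  # weighted variant with nearly all weight on one SNP tracks that ratio
  hw <- mk_hset(beta_exp = c(10, 0.1, 0.1), se_exp = 0.01,
                beta_out = c(5, 0.002, 0.009), se_out = 0.01)
  rw <- mr_mode(hw, weighted = TRUE, n_boot = 200, seed = 1)
  expect_equal(rw$beta, 0.5, tolerance = 0.05)
})

test_that("the estimator battery applies instrument-count minima", {
  h2 <- mk_hset(c(0.1, 0.2), 0.01, c(0.02, 0.05), 0.005)
  out <- mr_run_all(h2, seed = 1)
  expect_named(out$results, "ivw")
  expect_setequal(out$skipped$method,
                  c("mr_egger", "weighted_median", "simple_mode", "weighted_mode"))
  h5 <- worked_hset()
  out5 <- mr_run_all(h5, n_boot = 200, seed = 1)
  expect_setequal(names(out5$results),
                  c("ivw", "mr_egger", "weighted_median", "simple_mode",
                    "weighted_mode"))
  expect_equal(nrow(out5$skipped), 0)
  tab <- mr_results_table(out5$results)
  expect_equal(nrow(tab), 5)
  expect_true(all(c("beta", "or_", "extras_json") %in% names(tab)))
})

test_that("estimates are invariant to SNP order and per-SNP joint sign flips", {
  set.seed(33)
  h <- simulate_instruments(8, beta = 0.3, se_y = runif(8, 0.02, 0.1))
  base <- mr_run_all(h, n_boot = 150, seed = 5)$results
  perm <- mrchain:::subset_hset(h, sample(8))
  flip <- as.data.frame(h)
  sw <- sample(c(-1, 1), 8, replace = TRUE)
  flip$beta_exp <- flip$beta_exp * sw
  flip$beta_out <- flip$beta_out * sw
  flip <- structure(flip, class = class(h), exposure_id = "E", outcome_id = "O",
                    outcome_type = "quantitative", n_exp = 30000, n_out = 700000,
                    drop_log = mrchain:::empty_drop_log())
  for (variant in list(perm, flip)) {
    alt <- mr_run_all(variant, n_boot = 150, seed = 5)$results
    for (m in names(base)) {
      expect_equal(alt[[m]]$beta, base[[m]]$beta, tolerance = 1e-12)
    }
    expect_equal(alt$ivw$se, base$ivw$se, tolerance = 1e-12)
    expect_equal(alt$mr_egger$se, base$mr_egger$se, tolerance = 1e-12)
    expect_equal(alt$mr_egger$extras$intercept, base$mr_egger$extras$intercept,
                 tolerance = 1e-12)
  }
})

test_that("bootstrap standard errors are reproducible under a fixed seed", {
  h <- worked_hset()
  a <- mr_weighted_median(h, n_boot = 300, seed = 99)
  b <- mr_weighted_median(h, n_boot = 300, seed = 99)
  expect_identical(a$se, b$se)
  c1 <- mr_mode(h, n_boot = 300, seed = 99)
  c2 <- mr_mode(h, n_boot = 300, seed = 99)
  expect_identical(c1$se, c2$se)
  expect_false(identical(mr_weighted_median(h, n_boot = 300, seed = 100)$se,
                         a$se))
})

test_that("odds-ratio transform reproduces published-style intervals", {
  flat <- or_with_ci(0, 0.1)
  expect_equal(unname(flat["or"]), 1)
  expect_equal(unname(flat["ci_low"] * flat["ci_high"]), 1, tolerance = 1e-12)
  risk <- or_with_ci(0.1553, 0.0582)
  expect_equal(unname(risk["or"]), 1.168, tolerance = 1e-3)
  expect_equal(unname(risk["ci_low"]), 1.042, tolerance = 1e-3)
  expect_equal(unname(risk["ci_high"]), 1.309, tolerance = 1e-3)
  prot <- or_with_ci(-0.2703, 0.0839)
  expect_equal(unname(prot["or"]), 0.763, tolerance = 1e-3)
  expect_equal(unname(prot["ci_low"]), 0.648, tolerance = 1e-3)
  expect_equal(unname(prot["ci_high"]), 0.899, tolerance = 1e-3)
  expect_error(or_with_ci(0.1, 0), "se")
})
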