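# The five causal-effect estimators: Wald ratio (single SNP), IVW with
# multiplicative random effects, MR-Egger, weighted median, simple/weighted
# mode. All operate on a harmonized_set and return an mr_result on the beta
# (log-odds for binary outcomes) scale.

mr_result <- function(method, beta, se, pval, n_snp, exposure = NA, outcome = NA,
                      extras = list(), df = NULL) {
  ci <- beta + c(-1, 1) * 1.96 * se
  structure(list(method = method, beta = beta, se = se,
                 ci_low = ci[1], ci_high = ci[2], pval = pval, n_snp = n_snp,
                 exposure = exposure, outcome = outcome, extras = extras),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  or <- or_with_ci(x$beta, x$se)
  cat(sprintf("<mr_result> %s (%d SNPs): beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n           OR = %.3f (%.3f-%.3f)\n",
              x$method, x$n_snp, x$beta, x$se, x$ci_low, x$ci_high, x$pval,
              or["or"], or["ci_low"], or["ci_high"]))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  or <- or_with_ci(x$beta, x$se)
  data.frame(exposure = x$exposure, outcome = x$outcome, method = x$method,
             n_snp = x$n_snp, beta = x$beta, se = x$se, ci_low = x$ci_low,
             ci_high = x$ci_high, pval = x$pval,
             or_ = unname(or["or"]), or_low = unname(or["ci_low"]),
             or_high = unname(or["ci_high"]),
             extras_json = as.character(jsonlite::toJSON(x$extras, auto_unbox = TRUE,
                                                         digits = NA)),
             stringsAsFactors = FALSE)
}

hset_labels <- function(hset) {
  list(exposure = attr(hset, "exposure_id") %||% NA,
       outcome = attr(hset, "outcome_id") %||% NA)
}

#' Wald ratio estimate from a single instrument
#'
#' beta = beta_out / beta_exp with first-order delta-method standard error
#' se_out / |beta_exp| (the exposure uncertainty enters only at second order
#' and is ignored, the convention for single-SNP MR).
#'
#' @param beta_exp,se_exp SNP-exposure effect and its SE.
#' @param beta_out,se_out SNP-outcome effect and its SE.
#' @return An `mr_result` with method `"wald_ratio"`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (beta_exp == 0) stopf("wald_ratio: beta_exp must be nonzero")
  beta <- beta_out / beta_exp
  se <- se_out / abs(beta_exp)
  mr_result("wald_ratio", beta, se, 2 * stats::pnorm(-abs(beta / se)), 1L)
}

# shared plumbing: per-SNP ratios and inverse-variance weights
ratio_weights <- function(hset) {
  if (any(hset$beta_exp == 0)) stopf("estimators: beta_exp must be nonzero for ratio-based methods")
  list(ratio = hset$beta_out / hset$beta_exp,
       w = hset$beta_exp^2 / hset$se_out^2)
}

ivw_core <- function(beta_exp, beta_out, se_out) {
  w <- 1 / se_out^2
  swxx <- sum(w * beta_exp^2)
  beta <- sum(w * beta_exp * beta_out) / swxx
  q <- sum(w * (beta_out - beta * beta_exp)^2)
  list(beta = beta, se_fixed = sqrt(1 / swxx), q = q)
}

#' Inverse-variance weighted estimate with multiplicative random effects
#'
#' Weighted regression of the outcome effects on the exposure effects through
#' the origin with weights 1 / se_out^2 (equivalently the inverse-variance
#' weighted mean of the per-SNP Wald ratios). The fixed-effect standard error
#' is inflated by `max(1, sqrt(Q / (J - 1)))` — the multiplicative
#' random-effects model, never deflating below the fixed-effect SE. With a
#' single instrument the estimate delegates to [wald_ratio()].
#'
#' @param hset a [harmonize()]d instrument set.
#' @return An `mr_result` with method `"ivw"`; `extras` carries `q`, `q_df`,
#'   `q_pval` and the uninflated `se_fixed`.
#' @export
mr_ivw <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  lab <- hset_labels(hset)
  j <- nrow(hset)
  if (j < 1) stopf("mr_ivw: empty instrument set")
  if (j == 1) {
    res <- wald_ratio(hset$beta_exp, hset$se_exp, hset$beta_out, hset$se_out)
    res$exposure <- lab$exposure; res$outcome <- lab$outcome
    return(res)
  }
  if (all(hset$beta_exp == 0)) stopf("mr_ivw: all beta_exp are zero")
  core <- ivw_core(hset$beta_exp, hset$beta_out, hset$se_out)
  infl <- max(1, sqrt(core$q / (j - 1)))
  se <- core$se_fixed * infl
  mr_result("ivw", core$beta, se, 2 * stats::pnorm(-abs(core$beta / se)), j,
            lab$exposure, lab$outcome,
            extras = list(q = core$q, q_df = j - 1,
                          q_pval = stats::pchisq(core$q, j - 1, lower.tail = FALSE),
                          se_fixed = core$se_fixed))
}

#' MR-Egger regression
#'
#' Instruments are first oriented so that every SNP-exposure effect is
#' positive (jointly negating (beta_exp, beta_out) where needed; estimators
#' are invariant to this allele recoding but the Egger intercept is not).
#' Then a weighted linear regression of beta_out on beta_exp with an
#' unconstrained intercept, weights 1 / se_out^2. The slope is the causal
#' estimate; a nonzero intercept indicates directional horizontal pleiotropy.
#' Standard errors use the multiplicative random-effects inflation
#' `max(1, sqrt(RSS / (J - 2)))` and inference uses the t distribution with
#' J - 2 degrees of freedom.
#'
#' @param hset a [harmonize()]d instrument set with at least 3 instruments.
#' @return An `mr_result` with method `"mr_egger"`; `extras` carries
#'   `intercept`, `intercept_se`, `intercept_p`, `q`(residual heterogeneity)
#'   and `q_df`.
#' @export
mr_egger <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  j <- nrow(hset)
  if (j < 3) stopf("mr_egger: requires at least 3 instruments (got %d)", j)
  lab <- hset_labels(hset)
  flip <- sign(hset$beta_exp)
  flip[flip == 0] <- 1
  x <- hset$beta_exp * flip
  y <- hset$beta_out * flip
  w <- 1 / hset$se_out^2
  # closed-form weighted least squares with intercept
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  inter <- (swxx * swy - swx * swxy) / det
  rss <- sum(w * (y - inter - slope * x)^2)
  infl <- max(1, sqrt(rss / (j - 2)))
  se_slope <- sqrt(sw / det) * infl
  se_inter <- sqrt(swxx / det) * infl
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = j - 2)
  p_inter <- 2 * stats::pt(-abs(inter / se_inter), df = j - 2)
  mr_result("mr_egger", slope, se_slope, p_slope, j, lab$exposure, lab$outcome,
            extras = list(intercept = inter, intercept_se = se_inter,
                          intercept_p = p_inter, q = rss, q_df = j - 2))
}

# Weighted-median point estimate: order the ratios, take the cumulative
# standardized weight p_j = (S_j - w_j/2) / S_total, and interpolate linearly
# to the ratio at which p crosses 0.5.
weighted_median_est <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]; w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(p)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

boot_se <- function(hset, estimator, n_boot, seed) {
  j <- nrow(hset)
  with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(b) {
      be <- stats::rnorm(j, hset$beta_exp, hset$se_exp)
      bo <- stats::rnorm(j, hset$beta_out, hset$se_out)
      estimator(bo / be, be^2 / hset$se_out^2)
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted median estimator
#'
#' Consistent when instruments carrying at least half of the total
#' inverse-variance weight are valid. The point estimate interpolates the
#' weighted empirical quantile function of the per-SNP Wald ratios at
#' probability 0.5 (weights beta_exp^2 / se_out^2); the standard error comes
#' from a seeded parametric bootstrap that redraws beta_exp and beta_out from
#' normal distributions centred on the observed values.
#'
#' @param hset a [harmonize()]d instrument set with at least 3 instruments.
#' @param n_boot bootstrap iterations (default 1000; fewer than 100 warns).
#' @param seed bootstrap seed (mandatory in pipeline runs).
#' @return An `mr_result` with method `"weighted_median"`; `extras` records
#'   `n_boot` and `seed`.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(hset, "harmonized_set"))
  j <- nrow(hset)
  if (j < 3) stopf("mr_weighted_median: requires at least 3 instruments (got %d)", j)
  if (n_boot < 100) warnf("mr_weighted_median: n_boot < 100 gives unstable SEs")
  lab <- hset_labels(hset)
  rw <- ratio_weights(hset)
  beta <- weighted_median_est(rw$ratio, rw$w)
  se <- boot_se(hset, weighted_median_est, n_boot, seed)
  mr_result("weighted_median", beta, se, 2 * stats::pnorm(-abs(beta / se)), j,
            lab$exposure, lab$outcome,
            extras = list(n_boot = n_boot, seed = seed))
}

# Kernel-smoothed mode of the ratio distribution on a fine grid.
mode_est <- function(ratio, w, phi, grid_n = 512) {
  h <- phi * 0.9 * min(stats::sd(ratio), stats::IQR(ratio) / 1.349) *
    length(ratio)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(list(beta = ratio[1], h = 0))
  grid <- seq(min(ratio), max(ratio), length.out = grid_n)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm(g - ratio, sd = h)),
                 numeric(1))
  list(beta = grid[which.max(dens)], h = h)
}

#' Simple and weighted mode estimators
#'
#' The mode of a Gaussian-kernel-smoothed density over the per-SNP Wald
#' ratios, evaluated on a fine grid spanning the ratios. Bandwidth
#' `h = phi * 0.9 * min(sd, IQR/1.349) * J^(-1/5)`. The weighted variant
#' weights each kernel by the SNP's inverse-variance weight; the simple
#' variant weights all SNPs equally. Consistent when the largest group of
#' instruments sharing the same ratio (ZEMPA) is valid. SE by seeded
#' parametric bootstrap. When all ratios coincide (zero bandwidth) that common
#' ratio is returned.
#'
#' @inheritParams mr_weighted_median
#' @param weighted use inverse-variance kernel weights (`TRUE` = weighted
#'   mode, `FALSE` = simple mode).
#' @param phi bandwidth inflation factor (default 1).
#' @param grid_n density grid size (default 512).
#' @return An `mr_result` with method `"weighted_mode"` or `"simple_mode"`;
#'   `extras` records `phi`, `bandwidth`, `grid_n`, `n_boot`, `seed`.
#' @export
mr_mode <- function(hset, weighted = TRUE, phi = 1, n_boot = 1000, seed = NULL,
                    grid_n = 512) {
  stopifnot(inherits(hset, "harmonized_set"))
  j <- nrow(hset)
  if (j < 3) stopf("mr_mode: requires at least 3 instruments (got %d)", j)
  if (n_boot < 100) warnf("mr_mode: n_boot < 100 gives unstable SEs")
  lab <- hset_labels(hset)
  rw <- ratio_weights(hset)
  kernel_w <- if (weighted) rw$w else rep(1, j)
  fit <- mode_est(rw$ratio, kernel_w, phi, grid_n)
  est_fun <- function(ratio, w) {
    mode_est(ratio, if (weighted) w else rep(1, length(ratio)), phi, grid_n)$beta
  }
  se <- boot_se(hset, est_fun, n_boot, seed)
  method <- if (weighted) "weighted_mode" else "simple_mode"
  mr_result(method, fit$beta, se, 2 * stats::pnorm(-abs(fit$beta / se)), j,
            lab$exposure, lab$outcome,
            extras = list(phi = phi, bandwidth = fit$h, grid_n = grid_n,
                          n_boot = n_boot, seed = seed))
}

#' Run the full estimator battery
#'
#' IVW (or the Wald ratio when only one instrument is available) is always
#' computed; MR-Egger, weighted median and the two mode estimators are added
#' when the instrument count meets their minimum (3), otherwise a skip record
#' is logged.
#'
#' @inheritParams mr_weighted_median
#' @param phi mode-estimator bandwidth factor.
#' @return A list with `results` (named list of `mr_result`) and `skipped`
#'   (data.frame of method/reason for estimators not run).
#' @export
mr_run_all <- function(hset, n_boot = 1000, seed = NULL, phi = 1) {
  stopifnot(inherits(hset, "harmonized_set"))
  j <- nrow(hset)
  results <- list(ivw = mr_ivw(hset))
  skipped <- data.frame(method = character(), reason = character(),
                        stringsAsFactors = FALSE)
  if (j >= 3) {
    results$mr_egger <- mr_egger(hset)
    results$weighted_median <- mr_weighted_median(hset, n_boot, seed)
    results$simple_mode <- mr_mode(hset, weighted = FALSE, phi = phi,
                                   n_boot = n_boot, seed = seed)
    results$weighted_mode <- mr_mode(hset, weighted = TRUE, phi = phi,
                                     n_boot = n_boot, seed = seed)
  } else {
    reason <- sprintf("n_snp = %d below minimum 3", j)
    skipped <- data.frame(method = c("mr_egger", "weighted_median",
                                     "simple_mode", "weighted_mode"),
                          reason = reason, stringsAsFactors = FALSE)
  }
  list(results = results, skipped = skipped)
}

#' Odds ratio with 95% confidence interval from a log-odds estimate
#'
#' @param beta log-odds causal estimate.
#' @param se its standard error (> 0).
#' @return Named numeric vector `or`, `ci_low`, `ci_high` (exp of
#'   `beta +/- 1.96 se`).
#' @export
or_with_ci <- function(beta, se) {
  if (any(se <= 0)) stopf("or_with_ci: se must be > 0")
  c(or = exp(beta), ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se))
}

#' Serialize MR results to a flat table
#'
#' @param results a list of `mr_result` objects (nested lists are flattened).
#' @return data.frame with one row per result, columns `exposure`, `outcome`,
#'   `method`, `n_snp`, `beta`, `se`, `ci_low`, `ci_high`, `pval`, `or_`,
#'   `or_low`, `or_high`, `extras_json`.
#' @export
mr_results_table <- function(results) {
  if (inherits(results, "mr_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    if (inherits(r, "mr_result")) as.data.frame(r) else mr_results_table(r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
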