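# Heterogeneity, pleiotropy, outlier and influence diagnostics for one
# harmonized exposure-outcome analysis.

#' Cochran's Q heterogeneity test
#'
#' Q = sum over instruments of w_j (r_j - beta_fixed)^2 with Wald ratios r_j
#' and inverse-variance weights w_j = beta_exp^2 / se_out^2, where beta_fixed
#' is the fixed-effect IVW estimate; p from the chi-square distribution with
#' J - 1 degrees of freedom. p > 0.05 is conventionally read as no significant
#' heterogeneity.
#'
#' @param hset a [harmonize()]d instrument set with at least 2 instruments.
#' @return list(q, q_df, q_pval).
#' @export
cochran_q <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  j <- nrow(hset)
  if (j < 2) stopf("cochran_q: requires at least 2 instruments")
  core <- ivw_core(hset$beta_exp, hset$beta_out, hset$se_out)
  list(q = core$q, q_df = j - 1,
       q_pval = stats::pchisq(core$q, j - 1, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the random-effects IVW estimate excluding each instrument in
#' turn, to flag estimates driven by a single SNP.
#'
#' @param hset a [harmonize()]d instrument set with at least 3 instruments.
#' @return data.frame keyed by `excluded_snp` with columns `n_snp`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `pval`.
#' @export
leave_one_out <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  j <- nrow(hset)
  if (j < 3) stopf("leave_one_out: requires at least 3 instruments")
  rows <- lapply(seq_len(j), function(i) {
    res <- mr_ivw(subset_hset(hset, setdiff(seq_len(j), i)))
    data.frame(excluded_snp = hset$snp_id[i], n_snp = res$n_snp,
               beta = res$beta, se = res$se, ci_low = res$ci_low,
               ci_high = res$ci_high, pval = res$pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Leave-one-out fixed-effect IVW slopes in O(J) from the weighted totals.
loo_slopes <- function(x, y, w) {
  swxy <- sum(w * x * y)
  swxx <- sum(w * x^2)
  (swxy - w * x * y) / (swxx - w * x^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based test for horizontal-pleiotropy outliers. The observed
#' residual sum of squares is `RSS = sum_j w_j (beta_out_j - b_(-j) *
#' beta_exp_j)^2` with `w_j = 1 / se_out_j^2` and `b_(-j)` the leave-one-out
#' fixed-effect IVW slope. `n_sim` parametric simulations redraw
#' `beta_out*_j ~ N(b_(-j) beta_exp_j, se_out_j)` and
#' `beta_exp*_j ~ N(beta_exp_j, se_exp_j)` and recompute RSS with the same
#' leave-one-out rule; the global p-value is the add-one Monte-Carlo tail
#' probability `(1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1)`. Each SNP's observed
#' weighted residual is likewise compared to its own simulated distribution,
#' Bonferroni-adjusted by the instrument count; SNPs with adjusted p below
#' `alpha_outlier` are flagged. When outliers are flagged a distortion test
#' compares the shift in the IVW estimate after removing them against a null
#' built from removals of randomly chosen same-size SNP sets, and the
#' outlier-corrected IVW estimate is reported as an annex.
#'
#' @param hset a [harmonize()]d instrument set with at least 4 instruments.
#' @param n_sim simulations for the global and outlier tests (>= 1000
#'   recommended).
#' @param seed simulation seed.
#' @param alpha_outlier significance level for flagging outliers after
#'   Bonferroni adjustment (default 0.05).
#' @return list: `global_rss`, `global_p`, `n_sim`, `seed`, `outlier_table`
#'   (per-SNP raw and Bonferroni p, flag), `outliers` (flagged SNP ids),
#'   `distortion_p` (NULL when nothing flagged), `corrected` (IVW without the
#'   flagged SNPs, NULL when nothing flagged).
#' @export
mr_presso <- function(hset, n_sim = 1000, seed = NULL, alpha_outlier = 0.05) {
  stopifnot(inherits(hset, "harmonized_set"))
  j <- nrow(hset)
  if (j < 4) stopf("mr_presso: requires at least 4 instruments (got %d)", j)
  x <- hset$beta_exp; y <- hset$beta_out
  sx <- hset$se_exp; sy <- hset$se_out
  w <- 1 / sy^2
  b_loo <- loo_slopes(x, y, w)
  obs_res <- w * (y - b_loo * x)^2
  rss_obs <- sum(obs_res)

  sim <- with_seed(seed, {
    xs <- matrix(stats::rnorm(j * n_sim, mean = x, sd = sx), nrow = j)
    ys <- matrix(stats::rnorm(j * n_sim, mean = b_loo * x, sd = sy), nrow = j)
    swxy <- colSums(w * xs * ys)
    swxx <- colSums(w * xs^2)
    # leave-one-out slopes per simulation, vectorized across the J x n_sim grid
    b_mat <- (rep(swxy, each = j) - w * xs * ys) /
      (rep(swxx, each = j) - w * xs^2)
    res <- w * (ys - b_mat * xs)^2
    list(res = res, rss = colSums(res))
  })

  global_p <- (1 + sum(sim$rss >= rss_obs)) / (n_sim + 1)
  p_raw <- (1 + rowSums(sim$res >= obs_res)) / (n_sim + 1)
  p_adj <- pmin(1, p_raw * j)
  flagged <- which(p_adj < alpha_outlier)
  outlier_table <- data.frame(snp_id = hset$snp_id, residual = obs_res,
                              p_raw = p_raw, p_bonferroni = p_adj,
                              outlier = seq_len(j) %in% flagged,
                              stringsAsFactors = FALSE)

  distortion_p <- NULL
  corrected <- NULL
  if (length(flagged) > 0 && length(flagged) < j - 1) {
    beta_all <- ivw_core(x, y, sy)$beta
    keep <- setdiff(seq_len(j), flagged)
    corrected <- mr_ivw(subset_hset(hset, keep))
    d_obs <- corrected$beta - beta_all
    k <- length(flagged)
    d_null <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
      vapply(seq_len(n_sim), function(b) {
        drop <- sample.int(j, k)
        idx <- setdiff(seq_len(j), drop)
        ivw_core(x[idx], y[idx], sy[idx])$beta - beta_all
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
  }
  list(global_rss = rss_obs, global_p = global_p, n_sim = n_sim, seed = seed,
       outlier_table = outlier_table, outliers = hset$snp_id[flagged],
       distortion_p = distortion_p, corrected = corrected)
}

#' Scatter and funnel diagnostic tables
#'
#' Emits plain tables so plotting is a thin layer over them: `scatter_points`
#' holds the per-SNP (beta_exp, beta_out) pairs with their SE bars and
#' `scatter_lines` the fitted line per estimator (Egger keeps its intercept;
#' all other methods pass through the origin); `funnel_points` holds each
#' SNP's Wald ratio against its precision 1 / se_ratio, and `funnel_ref` the
#' IVW estimate for the vertical reference line.
#'
#' @param hset a [harmonize()]d instrument set.
#' @param results named list of `mr_result` objects (may be empty).
#' @return list(scatter_points, scatter_lines, funnel_points, funnel_ref).
#' @export
diagnostics_points <- function(hset, results = list()) {
  stopifnot(inherits(hset, "harmonized_set"))
  scatter_points <- data.frame(snp_id = hset$snp_id, beta_exp = hset$beta_exp,
                               se_exp = hset$se_exp, beta_out = hset$beta_out,
                               se_out = hset$se_out, stringsAsFactors = FALSE)
  scatter_lines <- do.call(rbind, lapply(results, function(r) {
    data.frame(method = r$method, slope = r$beta,
               intercept = r$extras$intercept %||% 0, stringsAsFactors = FALSE)
  }))
  if (is.null(scatter_lines)) {
    scatter_lines <- data.frame(method = character(), slope = numeric(),
                                intercept = numeric(), stringsAsFactors = FALSE)
  }
  se_ratio <- hset$se_out / abs(hset$beta_exp)
  funnel_points <- data.frame(snp_id = hset$snp_id,
                              ratio = hset$beta_out / hset$beta_exp,
                              precision = 1 / se_ratio, stringsAsFactors = FALSE)
  ivw_beta <- if (!is.null(results$ivw)) results$ivw$beta else
    if (nrow(hset) >= 2) ivw_core(hset$beta_exp, hset$beta_out, hset$se_out)$beta
    else funnel_points$ratio[1]
  rownames(scatter_lines) <- NULL
  list(scatter_points = scatter_points, scatter_lines = scatter_lines,
       funnel_points = funnel_points, funnel_ref = ivw_beta)
}

#' Full sensitivity battery for one analysis
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, MR-PRESSO (when at least
#' 4 instruments), leave-one-out (at least 3) and the scatter/funnel tables
#' into one report.
#'
#' @inheritParams mr_presso
#' @param results optional precomputed `mr_run_all()` results (recomputed if
#'   omitted).
#' @return A `sensitivity_report` list: `q`, `q_df`, `q_pval`,
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_p`,
#'   `presso` (or NULL), `loo` (or NULL), `funnel_points`, `scatter_points`,
#'   `scatter_lines`, `funnel_ref`, `seed`.
#' @export
sensitivity_report <- function(hset, results = NULL, n_sim = 1000, seed = NULL,
                               alpha_outlier = 0.05) {
  stopifnot(inherits(hset, "harmonized_set"))
  j <- nrow(hset)
  if (is.null(results)) results <- mr_run_all(hset, seed = seed)$results
  qres <- if (j >= 2) cochran_q(hset) else list(q = NA, q_df = NA, q_pval = NA)
  egger <- results$mr_egger
  presso <- if (j >= 4) mr_presso(hset, n_sim = n_sim, seed = seed,
                                  alpha_outlier = alpha_outlier) else NULL
  loo <- if (j >= 3) leave_one_out(hset) else NULL
  diag <- diagnostics_points(hset, results)
  structure(list(
    q = qres$q, q_df = qres$q_df, q_pval = qres$q_pval,
    egger_intercept = if (!is.null(egger)) egger$extras$intercept else NA,
    egger_intercept_se = if (!is.null(egger)) egger$extras$intercept_se else NA,
    egger_intercept_p = if (!is.null(egger)) egger$extras$intercept_p else NA,
    presso = presso, loo = loo,
    scatter_points = diag$scatter_points, scatter_lines = diag$scatter_lines,
    funnel_points = diag$funnel_points, funnel_ref = diag$funnel_ref,
    seed = seed
  ), class = "sensitivity_report")
}

#' Write a sensitivity report as JSON plus companion TSV tables
#'
#' @param report a [sensitivity_report()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return the directory, invisibly.
#' @export
write_sensitivity_report <- function(report, dir, prefix = "sensitivity") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(q = report$q, q_df = report$q_df, q_pval = report$q_pval,
                  egger_intercept = report$egger_intercept,
                  egger_intercept_se = report$egger_intercept_se,
                  egger_intercept_p = report$egger_intercept_p,
                  presso_global_p = report$presso$global_p %||% NA,
                  presso_outliers = report$presso$outliers %||% character(0),
                  presso_distortion_p = report$presso$distortion_p %||% NA,
                  seed = report$seed %||% NA)
  jsonlite::write_json(summary, file.path(dir, paste0(prefix, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  wr <- function(tab, name) {
    if (!is.null(tab)) {
      utils::write.table(tab, file.path(dir, paste0(prefix, "_", name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  wr(report$loo, "loo")
  wr(report$scatter_points, "scatter")
  wr(report$funnel_points, "funnel")
  invisible(dir)
}
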