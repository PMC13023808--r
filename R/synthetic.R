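# Synthetic three-layer GWAS generator: a quantitative exposure (cis-eQTL
# style), a quantitative mediator (microbiome-abundance style) and a binary
# outcome (liability-threshold case/control GWAS), linked by a causal chain
# exposure -> mediator -> outcome with a known truth record. Two engines: a
# fast analytic engine that draws observed effects around their expected
# marginal values, and an individual-level engine that simulates genotypes and
# phenotypes explicitly (used to validate the analytic one).

#' Configuration for the chain simulator
#'
#' Defaults mirror the shape of the source data layers: an expression
#' exposure instrumented by ~10 cis SNPs at eQTLGen-like sample size
#' (n = 30,000), a microbiome-abundance mediator measured in 5,959 individuals
#' with p < 5e-6-grade instruments, and a case/control liver-disease outcome
#' with 8,434 cases among 778,614 individuals.
#'
#' @param j_exp,j_med instrument counts for the exposure and the mediator.
#' @param maf_range minor-allele-frequency interval, inside (0, 0.5].
#' @param var_explained_exp,var_explained_med total variance in the exposure
#'   (resp. mediator) explained by its own instruments, in (0, 1).
#' @param beta1 exposure -> mediator causal effect (per SD of exposure).
#' @param beta2 mediator -> outcome causal effect on the liability scale
#'   (summary effects are emitted on the log-odds scale).
#' @param beta_direct exposure -> outcome direct (non-mediated) liability
#'   effect.
#' @param pleio_mean,pleio_sd per-SNP direct-on-outcome pleiotropy for the
#'   exposure instruments (liability scale); (0, 0) = no pleiotropy,
#'   mean != 0 = directional, sd > 0 with mean 0 = balanced (InSIDE holds
#'   since draws are independent of instrument strength).
#' @param n_exp,n_med,n_out GWAS sample sizes; `n_cases_out` cases for the
#'   binary outcome.
#' @param ld_block_r2,ld_block_size optional exchangeable LD: consecutive
#'   blocks of `ld_block_size` SNPs share squared correlation `ld_block_r2`;
#'   both NULL (default) gives an identity LD matrix.
#' @param engine `"analytic"` or `"individual"`.
#' @param seed integer seed; identical seeds give bit-identical studies.
#' @return A `chain_sim_config` list.
#' @export
chain_sim_config <- function(j_exp = 10, j_med = 15,
                             maf_range = c(0.05, 0.5),
                             var_explained_exp = 0.10,
                             var_explained_med = 0.05,
                             beta1 = 0.2, beta2 = 0.5, beta_direct = 0.15,
                             pleio_mean = 0, pleio_sd = 0,
                             n_exp = 30000, n_med = 5959,
                             n_out = 778614, n_cases_out = 8434,
                             ld_block_r2 = NULL, ld_block_size = NULL,
                             engine = c("analytic", "individual"), seed = 1L) {
  engine <- match.arg(engine)
  stopifnot(j_exp >= 1, j_med >= 1,
            var_explained_exp > 0, var_explained_exp < 1,
            var_explained_med > 0, var_explained_med < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_exp > 2, n_med > 2, n_out > 2,
            n_cases_out > 0, n_cases_out < n_out)
  structure(as.list(environment()), class = "chain_sim_config")
}

# liability-scale effect -> log-odds scale conversion constant for a
# liability-threshold trait with prevalence k: small-effect approximation
# logOR ~= beta_liability * phi(t) / (k (1 - k)), t the threshold.
liability_to_logodds <- function(k) {
  t <- stats::qnorm(1 - k)
  stats::dnorm(t) / (k * (1 - k))
}

non_palindromic_pairs <- rbind(
  c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
  c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T")
)

make_table <- function(snp, beta_obs, se, n, trait_id, trait_type, n_cases = NULL,
                       provenance) {
  gwas_table(data.frame(
    snp_id = snp$snp_id, chrom = snp$chrom, pos = snp$pos,
    effect_allele = snp$ea, other_allele = snp$oa, eaf = snp$maf,
    beta = beta_obs, se = se, pval = 2 * stats::pnorm(-abs(beta_obs / se)),
    n = n, stringsAsFactors = FALSE
  ), trait_id = trait_id, trait_type = trait_type, n_cases = n_cases,
  provenance = provenance)
}

#' Simulate a three-layer GWAS summary-statistics study with known truth
#'
#' Draws MAFs and per-SNP true effects (random signs, uniform magnitudes)
#' scaled so the instruments jointly explain the configured variance in their
#' own trait; every SNP appears in all three GWAS tables. True marginal
#' effects follow the chain: exposure SNPs act on the mediator via `beta1` and
#' on the outcome liability via `beta_direct + beta1 * beta2` plus their
#' per-SNP pleiotropy draw; mediator SNPs act on the outcome via `beta2`.
#' All traits are standardized to unit variance; the binary outcome arises
#' from a liability threshold at prevalence `n_cases_out / n_out`.
#'
#' The analytic engine sets each standard error from the sample size and
#' allele frequency (`1 / sqrt(2 p (1-p) n)` for quantitative traits,
#' additionally scaled by case/control balance `1 / sqrt(k (1-k))` on the
#' log-odds scale for the binary outcome, with liability effects mapped to
#' log-odds by `phi(t) / (k (1-k))`), then samples observed beta ~
#' N(true, se). The individual engine simulates genotypes and phenotypes
#' explicitly and fits per-SNP linear (quantitative) or logistic (binary)
#' regressions; it refuses n > 50,000 and exists to validate the analytic
#' engine.
#'
#' @param config a [chain_sim_config()].
#' @return A `synthetic_study` list: `exposure_gwas`, `mediator_gwas`,
#'   `outcome_gwas` (validated [gwas_table()]s), `ld` (an [ld_matrix()] or
#'   NULL), and `truth` — all generating parameters, the per-SNP true effects,
#'   the derived true total effect `beta_direct + beta1 * beta2` and true
#'   mediation proportion `beta1 * beta2 / total`, and a `violations` log
#'   (filled by [plant_violations()]).
#' @export
simulate_chain <- function(config) {
  stopifnot(inherits(config, "chain_sim_config"))
  with_seed(config$seed, simulate_chain_impl(config))
}

simulate_chain_impl <- function(cfg) {
  j <- cfg$j_exp + cfg$j_med
  is_exp <- seq_len(j) <= cfg$j_exp
  maf <- stats::runif(j, cfg$maf_range[1], cfg$maf_range[2])
  var_per_allele <- 2 * maf * (1 - maf)
  pair <- non_palindromic_pairs[sample.int(nrow(non_palindromic_pairs), j,
                                           replace = TRUE), , drop = FALSE]
  snp <- data.frame(
    snp_id = sprintf("rs%06d", sample.int(999999, j)),
    chrom = ifelse(is_exp, "1", as.character(1 + (seq_len(j) %% 21) + 1)),
    pos = ifelse(is_exp,
                 1e6 + (seq_len(j)) * 5e4,        # cis window on chr 1
                 round(stats::runif(j, 1e6, 1e8))),
    ea = pair[, 1], oa = pair[, 2], maf = maf, stringsAsFactors = FALSE
  )

  scale_effects <- function(idx, target) {
    mag <- stats::runif(length(idx), 0.5, 1.5) * sample(c(-1, 1), length(idx),
                                                        replace = TRUE)
    mag * sqrt(target / sum(var_per_allele[idx] * mag^2))
  }
  a <- numeric(j); b <- numeric(j)
  a[is_exp] <- scale_effects(which(is_exp), cfg$var_explained_exp)
  b[!is_exp] <- scale_effects(which(!is_exp), cfg$var_explained_med)
  pleio <- numeric(j)
  if (cfg$pleio_mean != 0 || cfg$pleio_sd > 0) {
    pleio[is_exp] <- stats::rnorm(cfg$j_exp, cfg$pleio_mean, cfg$pleio_sd)
  }

  total <- cfg$beta_direct + cfg$beta1 * cfg$beta2
  true_exp <- a
  true_med <- a * cfg$beta1 + b
  true_out_liab <- a * total + pleio + b * cfg$beta2
  k <- cfg$n_cases_out / cfg$n_out
  c_l2o <- liability_to_logodds(k)

  if (cfg$engine == "analytic") {
    se_exp <- 1 / sqrt(var_per_allele * cfg$n_exp)
    se_med <- 1 / sqrt(var_per_allele * cfg$n_med)
    se_out <- 1 / sqrt(var_per_allele * cfg$n_out * k * (1 - k))
    beta_exp <- stats::rnorm(j, true_exp, se_exp)
    beta_med <- stats::rnorm(j, true_med, se_med)
    beta_out <- stats::rnorm(j, true_out_liab * c_l2o, se_out)
  } else {
    fits <- simulate_individual(cfg, snp, a, b, pleio, k)
    beta_exp <- fits$beta_exp; se_exp <- fits$se_exp
    beta_med <- fits$beta_med; se_med <- fits$se_med
    beta_out <- fits$beta_out; se_out <- fits$se_out
  }

  ld <- NULL
  if (!is.null(cfg$ld_block_r2) && !is.null(cfg$ld_block_size)) {
    block <- (seq_len(j) - 1) %/% cfg$ld_block_size
    m <- outer(block, block, "==") * cfg$ld_block_r2
    diag(m) <- 1
    ld <- ld_matrix(m, snp$snp_id)
  }

  truth <- list(
    config = unclass(cfg),
    snp_id = snp$snp_id, is_exposure_instrument = is_exp, maf = maf,
    effect_exposure = a, effect_mediator = b, pleiotropy = pleio,
    true_marginal_exposure = true_exp, true_marginal_mediator = true_med,
    true_marginal_outcome_liability = true_out_liab,
    prevalence = k, liability_to_logodds = c_l2o,
    beta1 = cfg$beta1, beta2 = cfg$beta2, beta_direct = cfg$beta_direct,
    total = total, indirect = cfg$beta1 * cfg$beta2,
    proportion = if (total != 0) cfg$beta1 * cfg$beta2 / total else NA_real_,
    violations = data.frame(snp_id = character(), type = character(),
                            stringsAsFactors = FALSE)
  )

  structure(list(
    exposure_gwas = make_table(snp, beta_exp, se_exp, cfg$n_exp, "exposure",
                               "quantitative", provenance = "synthetic"),
    mediator_gwas = make_table(snp, beta_med, se_med, cfg$n_med, "mediator",
                               "quantitative", provenance = "synthetic"),
    outcome_gwas = make_table(snp, beta_out, se_out, cfg$n_out, "outcome",
                              "binary", n_cases = cfg$n_cases_out,
                              provenance = "synthetic"),
    ld = ld, truth = truth
  ), class = "synthetic_study")
}

# Individual-level engine: explicit genotypes, unit-variance phenotypes,
# liability-threshold case/control outcome, per-SNP marginal regressions.
simulate_individual <- function(cfg, snp, a, b, pleio, k) {
  n <- max(cfg$n_exp, cfg$n_med, cfg$n_out)
  if (n > 50000) {
    stopf("simulate_chain: individual engine supports n <= 50,000 (got %d); use the analytic engine at scale", n)
  }
  j <- nrow(snp)
  sim_cohort <- function(n) {
    g <- vapply(snp$maf, function(p) stats::rbinom(n, 2, p), numeric(n))
    x <- g %*% a + stats::rnorm(n, 0, sqrt(max(1 - cfg$var_explained_exp, 0.02)))
    var_m_resid <- max(1 - cfg$beta1^2 - cfg$var_explained_med, 0.02)
    m <- cfg$beta1 * x + g %*% b + stats::rnorm(n, 0, sqrt(var_m_resid))
    var_liab_expl <- cfg$beta_direct^2 + cfg$beta2^2 +
      2 * cfg$beta_direct * cfg$beta2 * cfg$beta1 + sum(pleio^2 * 2 * snp$maf * (1 - snp$maf))
    liab <- cfg$beta_direct * x + cfg$beta2 * m + g %*% pleio +
      stats::rnorm(n, 0, sqrt(max(1 - var_liab_expl, 0.02)))
    list(g = g, x = as.numeric(x), m = as.numeric(m), liab = as.numeric(liab))
  }
  fit_quant <- function(g, y, nn) {
    out <- vapply(seq_len(j), function(i) {
      f <- stats::lm.fit(cbind(1, g[seq_len(nn), i]), y[seq_len(nn)])
      beta <- f$coefficients[2]
      sigma2 <- sum(f$residuals^2) / f$df.residual
      se <- sqrt(sigma2 / sum((g[seq_len(nn), i] - mean(g[seq_len(nn), i]))^2))
      c(beta, se)
    }, numeric(2))
    list(beta = out[1, ], se = out[2, ])
  }
  co <- sim_cohort(n)
  fe <- fit_quant(co$g, co$x, cfg$n_exp)
  fm <- fit_quant(co$g, co$m, cfg$n_med)
  thr <- stats::quantile(co$liab[seq_len(cfg$n_out)], 1 - k)
  case <- as.integer(co$liab[seq_len(cfg$n_out)] > thr)
  fo <- vapply(seq_len(j), function(i) {
    f <- suppressWarnings(stats::glm.fit(cbind(1, co$g[seq_len(cfg$n_out), i]),
                                         case, family = stats::binomial()))
    cf <- f$coefficients[2]
    # SE from the inverse Fisher information at the fit
    p <- f$fitted.values
    xg <- co$g[seq_len(cfg$n_out), i]
    wi <- p * (1 - p)
    xtx <- matrix(c(sum(wi), sum(wi * xg), sum(wi * xg), sum(wi * xg^2)), 2)
    c(cf, sqrt(solve(xtx)[2, 2]))
  }, numeric(2))
  list(beta_exp = fe$beta, se_exp = fe$se,
       beta_med = fm$beta, se_med = fm$se,
       beta_out = fo[1, ], se_out = fo[2, ])
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d exposure + %d mediator instruments; true total %.4f, proportion mediated %.1f%%\n",
              x$truth$config$j_exp, x$truth$config$j_med, x$truth$total,
              100 * x$truth$proportion))
  invisible(x)
}

replace_rows <- function(table, idx, values) {
  df <- as.data.frame(table)
  for (nm in names(values)) df[idx, nm] <- values[[nm]]
  df$pval <- 2 * stats::pnorm(-abs(df$beta / df$se))
  structure(df, class = class(table), trait_id = attr(table, "trait_id"),
            trait_type = attr(table, "trait_type"),
            provenance = attr(table, "provenance"),
            drop_log = drop_log(table))
}

#' Plant named quality-control defects into a synthetic study
#'
#' Injects defects used to exercise the QC filters and sensitivity
#' diagnostics, each drawn from distinct exposure instruments and logged in
#' `truth$violations`:
#' \describe{
#'   \item{outlier}{`n_outlier` SNPs whose observed outcome effect is set to
#'     `outlier_ratio_mult` times the true total effect times the observed
#'     exposure effect, with the outcome SE halved (a gross
#'     horizontal-pleiotropy outlier for MR-PRESSO).}
#'   \item{weak}{`n_weak` SNPs whose exposure effect is redrawn so that
#'     F = (beta/se)^2 lands in (2, 8), below the conventional threshold 10.}
#'   \item{pleiotropy}{`n_pleio` SNPs whose outcome effect is shifted by
#'     `pleio_shift` (directional pleiotropy on the log-odds scale).}
#'   \item{reverse}{`n_reverse` SNPs rewritten as reverse-causal: modest
#'     exposure association (Z around `z_exp_reverse`) but an outcome
#'     association strong enough to explain more outcome than exposure
#'     variance, so Steiger filtering should remove them.}
#'   \item{palindrome}{`n_palindrome` SNPs recoded to an A/T allele pair with
#'     allele frequency `palindrome_eaf` in every table, making strand
#'     orientation unresolvable at the default frequency band.}
#' }
#'
#' @param study a [simulate_chain()] result.
#' @param n_outlier,n_weak,n_pleio,n_reverse,n_palindrome defect counts.
#' @param outlier_ratio_mult Wald-ratio multiple for the planted outlier.
#' @param pleio_shift log-odds shift for directional pleiotropy.
#' @param z_exp_reverse exposure-side Z for reverse-causal SNPs.
#' @param palindrome_eaf allele frequency given to palindromic recodes.
#' @param seed seed for choosing which SNPs to corrupt and for redraws.
#' @return The modified `synthetic_study`; `truth$violations` lists each
#'   planted defect.
#' @export
plant_violations <- function(study, n_outlier = 0, n_weak = 0, n_pleio = 0,
                             n_reverse = 0, n_palindrome = 0,
                             outlier_ratio_mult = 10, pleio_shift = 0.1,
                             z_exp_reverse = 6, palindrome_eaf = 0.49,
                             seed = 1L) {
  stopifnot(inherits(study, "synthetic_study"))
  n_total <- n_outlier + n_weak + n_pleio + n_reverse + n_palindrome
  exp_idx <- which(study$truth$is_exposure_instrument)
  if (n_total > length(exp_idx)) {
    stopf("plant_violations: %d defects requested but only %d exposure instruments exist",
          n_total, length(exp_idx))
  }
  if (n_total == 0) return(study)
  with_seed(seed, {
    chosen <- sample(exp_idx, n_total)
    take <- function(k) {
      out <- chosen[seq_len(k)]
      chosen <<- chosen[-seq_len(k)]
      out
    }
    log <- study$truth$violations
    e <- as.data.frame(study$exposure_gwas)
    o <- as.data.frame(study$outcome_gwas)

    if (n_outlier > 0) {
      idx <- take(n_outlier)
      study$outcome_gwas <- replace_rows(
        study$outcome_gwas, idx,
        list(beta = outlier_ratio_mult * study$truth$total *
               study$truth$liability_to_logodds * e$beta[idx],
             se = o$se[idx] / 2))
      log <- rbind(log, data.frame(snp_id = e$snp_id[idx], type = "outlier"))
    }
    if (n_weak > 0) {
      idx <- take(n_weak)
      f_target <- stats::runif(n_weak, 2, 8)
      study$exposure_gwas <- replace_rows(
        study$exposure_gwas, idx,
        list(beta = sign(e$beta[idx]) * e$se[idx] * sqrt(f_target)))
      log <- rbind(log, data.frame(snp_id = e$snp_id[idx], type = "weak"))
    }
    if (n_pleio > 0) {
      idx <- take(n_pleio)
      study$outcome_gwas <- replace_rows(study$outcome_gwas, idx,
                                         list(beta = o$beta[idx] + pleio_shift))
      log <- rbind(log, data.frame(snp_id = e$snp_id[idx], type = "pleiotropy"))
    }
    if (n_reverse > 0) {
      idx <- take(n_reverse)
      n_exp <- study$truth$config$n_exp
      n_out <- study$truth$config$n_out
      # outcome Z chosen so r2_out is ~4x r2_exp at the planted exposure Z
      z_out <- 2 * sqrt(z_exp_reverse^2 * n_out / n_exp)
      sgn <- sign(e$beta[idx])
      study$exposure_gwas <- replace_rows(
        study$exposure_gwas, idx,
        list(beta = stats::rnorm(n_reverse, sgn * e$se[idx] * z_exp_reverse,
                                 e$se[idx])))
      study$outcome_gwas <- replace_rows(
        study$outcome_gwas, idx,
        list(beta = stats::rnorm(n_reverse, sgn * o$se[idx] * z_out, o$se[idx])))
      log <- rbind(log, data.frame(snp_id = e$snp_id[idx], type = "reverse"))
    }
    if (n_palindrome > 0) {
      idx <- take(n_palindrome)
      recode <- list(effect_allele = "A", other_allele = "T",
                     eaf = palindrome_eaf)
      study$exposure_gwas <- replace_rows(study$exposure_gwas, idx, recode)
      study$mediator_gwas <- replace_rows(study$mediator_gwas, idx, recode)
      study$outcome_gwas <- replace_rows(study$outcome_gwas, idx, recode)
      log <- rbind(log, data.frame(snp_id = e$snp_id[idx], type = "palindrome"))
    }
    study$truth$violations <- log
    study
  })
}

#' Simulate one harmonized instrument set with known causal effect
#'
#' Instrument-level generator for estimator calibration studies: draws true
#' SNP-exposure effects with random signs and magnitudes in `x_range`, observed
#' exposure effects `~ N(true, se_x)`, and observed outcome effects
#' `~ N(beta * true + pleiotropy, se_y)` with per-SNP pleiotropy
#' `~ N(pleio_mean, pleio_sd)` drawn independently of instrument strength (so
#' InSIDE holds). Unlike [simulate_chain()] this skips the trait layer
#' entirely: the truth is `beta` on the estimator's own scale, which makes it
#' the right harness for bias, type-I-error and intercept-recovery studies.
#'
#' @param j number of instruments.
#' @param beta true causal effect.
#' @param x_range magnitude range of the true SNP-exposure effects.
#' @param se_x,se_y standard errors of the observed exposure and outcome
#'   effects (scalars or length-j vectors).
#' @param pleio_mean,pleio_sd per-SNP pleiotropy distribution (0, 0 = none).
#' @param n_exp,n_out nominal sample sizes carried on the set (used only by
#'   Steiger filtering).
#' @return A `harmonized_set`.
#' @export
simulate_instruments <- function(j, beta = 0, x_range = c(0.1, 0.3),
                                 se_x = 0.005, se_y = 0.05,
                                 pleio_mean = 0, pleio_sd = 0,
                                 n_exp = 30000, n_out = 700000) {
  x_true <- stats::runif(j, x_range[1], x_range[2]) *
    sample(c(-1, 1), j, replace = TRUE)
  se_x <- rep_len(se_x, j)
  se_y <- rep_len(se_y, j)
  pleio <- if (pleio_mean != 0 || pleio_sd > 0) {
    stats::rnorm(j, pleio_mean, pleio_sd) * sign(x_true)
  } else numeric(j)
  # pleiotropy acts on the oriented (beta_exp > 0) scale: sign(x) keeps the
  # planted directional mean visible to the Egger intercept after orientation
  h <- data.frame(
    snp_id = sprintf("snp%03d", seq_len(j)), chrom = "1",
    pos = seq_len(j) * 1e5, effect_allele = "A", other_allele = "G",
    beta_exp = stats::rnorm(j, x_true, se_x), se_exp = se_x,
    pval_exp = 1e-12, eaf = 0.3,
    beta_out = stats::rnorm(j, beta * x_true + pleio, se_y), se_out = se_y,
    pval_out = 0.5, eaf_out = 0.3, stringsAsFactors = FALSE
  )
  structure(h, class = c("harmonized_set", "data.frame"),
            exposure_id = "sim_exposure", outcome_id = "sim_outcome",
            outcome_type = "quantitative", n_exp = n_exp, n_out = n_out,
            drop_log = empty_drop_log())
}

#' Write a synthetic study to disk
#'
#' Emits the three GWAS tables as canonical TSVs, the LD matrix (if any) as a
#' square matrix file, and the truth record as JSON.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gwas_table(study$exposure_gwas, file.path(dir, "exposure.tsv"))
  write_gwas_table(study$mediator_gwas, file.path(dir, "mediator.tsv"))
  write_gwas_table(study$outcome_gwas, file.path(dir, "outcome.tsv"))
  if (!is.null(study$ld)) {
    utils::write.table(as.data.frame(unclass(study$ld)),
                       file.path(dir, "ld.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
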