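# Two-step MR mediation: decompose a total causal effect into the indirect
# component running through one mediator (product of coefficients) and the
# direct remainder, with delta-method (propagation of error) uncertainty.

#' Two-step MR mediation decomposition
#'
#' Given three MR estimates on the beta (log-odds where applicable) scale —
#' the total effect of the exposure on the outcome (beta_all), the
#' exposure-on-mediator effect (beta1) and the mediator-on-outcome effect
#' (beta2) — computes:
#' indirect = beta1 * beta2, with first-order propagation-of-error SE
#' `sqrt(beta1^2 se2^2 + beta2^2 se1^2)` (optionally adding the second-order
#' term `se1^2 se2^2`); direct = beta_all - indirect with
#' `sqrt(se_all^2 + se_indirect^2)` under independence of the two estimates
#' (conservative when they are positively correlated); proportion mediated =
#' indirect / beta_all with the ratio delta-method SE
#' `|proportion| * sqrt((se_ind/indirect)^2 + (se_all/beta_all)^2)`. All 95%
#' CIs are estimate ± 1.96 SE; the indirect-effect p-value is a two-sided
#' normal test. Proportions outside \[0, 1\] are reported as computed with the
#' flag `"inconsistent_mediation"` (never truncated).
#'
#' @param total `mr_result` for exposure -> outcome (the total effect).
#' @param step1 `mr_result` for exposure -> mediator (beta1).
#' @param step2 `mr_result` for mediator -> outcome (beta2).
#' @param second_order include the second-order `se1^2 * se2^2` term in the
#'   indirect-effect variance (default FALSE, the common two-step MR
#'   convention).
#' @param check_labels verify that the three results form a coherent
#'   exposure -> mediator -> outcome triple (default TRUE; mismatch is fatal).
#' @return A `mediation_result` list: trait labels; `beta_total`, `beta1`,
#'   `beta2` with SEs; `indirect`, `se_indirect`, `ci_indirect`, `p_indirect`;
#'   `direct`, `se_direct`, `ci_direct`; `proportion`, `se_proportion`,
#'   `ci_proportion` (all NA with a reason when `beta_total` is 0); `flags`;
#'   `methods_used`.
#' @export
two_step_mediation <- function(total, step1, step2, second_order = FALSE,
                               check_labels = TRUE) {
  stopifnot(inherits(total, "mr_result"), inherits(step1, "mr_result"),
            inherits(step2, "mr_result"))
  if (check_labels) {
    ok <- identical(total$exposure, step1$exposure) &&
      identical(step1$outcome, step2$exposure) &&
      identical(total$outcome, step2$outcome)
    if (!ok && !(is.na(total$exposure) && is.na(step1$exposure))) {
      stopf("two_step_mediation: trait labels do not form a chain (%s->%s, %s->%s, %s->%s)",
            total$exposure, total$outcome, step1$exposure, step1$outcome,
            step2$exposure, step2$outcome)
    }
  }
  b_all <- total$beta; se_all <- total$se
  b1 <- step1$beta; se1 <- step1$se
  b2 <- step2$beta; se2 <- step2$se

  indirect <- b1 * b2
  var_ind <- b1^2 * se2^2 + b2^2 * se1^2
  if (second_order) var_ind <- var_ind + se1^2 * se2^2
  se_ind <- sqrt(var_ind)
  p_ind <- if (se_ind > 0) 2 * stats::pnorm(-abs(indirect / se_ind)) else
    as.numeric(indirect == 0)

  direct <- b_all - indirect
  se_dir <- sqrt(se_all^2 + se_ind^2)

  flags <- character(0)
  if (b_all == 0) {
    proportion <- NA_real_; se_prop <- NA_real_
    flags <- c(flags, "proportion_undefined_zero_total")
  } else {
    proportion <- indirect / b_all
    se_prop <- if (indirect != 0) {
      abs(proportion) * sqrt((se_ind / indirect)^2 + (se_all / b_all)^2)
    } else {
      # limit of the ratio delta method as indirect -> 0
      se_ind / abs(b_all)
    }
    if (proportion < 0 || proportion > 1) {
      flags <- c(flags, "inconsistent_mediation")
    }
  }

  structure(list(
    exposure_id = total$exposure, mediator_id = step1$outcome,
    outcome_id = total$outcome,
    beta_total = b_all, se_total = se_all,
    beta1 = b1, se1 = se1, beta2 = b2, se2 = se2,
    indirect = indirect, se_indirect = se_ind,
    ci_indirect = indirect + c(-1, 1) * 1.96 * se_ind,
    p_indirect = p_ind,
    direct = direct, se_direct = se_dir,
    ci_direct = direct + c(-1, 1) * 1.96 * se_dir,
    proportion = proportion, se_proportion = se_prop,
    ci_proportion = if (is.na(proportion)) c(NA_real_, NA_real_) else
      proportion + c(-1, 1) * 1.96 * se_prop,
    flags = flags, second_order = second_order,
    methods_used = c(total = total$method, step1 = step1$method,
                     step2 = step2$method)
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s -> %s -> %s\n", x$exposure_id,
              x$mediator_id, x$outcome_id))
  cat(sprintf("  total    %8.4f (se %.4f)\n", x$beta_total, x$se_total))
  cat(sprintf("  indirect %8.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$indirect, x$se_indirect, x$ci_indirect[1], x$ci_indirect[2],
              x$p_indirect))
  cat(sprintf("  direct   %8.4f (se %.4f)\n", x$direct, x$se_direct))
  if (!is.na(x$proportion)) {
    cat(sprintf("  proportion mediated %.1f%% (se %.1f%%)%s\n",
                100 * x$proportion, 100 * x$se_proportion,
                if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
                else ""))
  }
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(exposure = x$exposure_id, mediator = x$mediator_id,
             outcome = x$outcome_id, beta_total = x$beta_total,
             se_total = x$se_total, beta1 = x$beta1, se1 = x$se1,
             beta2 = x$beta2, se2 = x$se2, indirect = x$indirect,
             se_indirect = x$se_indirect, ci_ind_low = x$ci_indirect[1],
             ci_ind_high = x$ci_indirect[2], p_indirect = x$p_indirect,
             direct = x$direct, se_direct = x$se_direct,
             proportion = x$proportion, se_proportion = x$se_proportion,
             flags = paste(x$flags, collapse = ";"), stringsAsFactors = FALSE)
}

#' Screen exposure-mediator-outcome triples for mediation analysis
#'
#' A triple qualifies when all three IVW links are nominally significant:
#' exposure -> outcome p < alpha, mediator -> outcome p < alpha, and
#' exposure -> mediator p < alpha.
#'
#' @param store data.frame of MR results with columns `exposure`, `outcome`,
#'   `pval` (e.g. from [mr_results_table()] filtered to one method), covering
#'   the exposure->outcome, mediator->outcome and exposure->mediator analyses.
#' @param outcome_id label of the final outcome trait.
#' @param alpha screening significance level (default 0.05).
#' @return data.frame of qualifying triples (`exposure`, `mediator`,
#'   `outcome`), with the qualifying link p-values.
#' @export
mediation_screen <- function(store, outcome_id, alpha = 0.05) {
  stopifnot(is.data.frame(store),
            all(c("exposure", "outcome", "pval") %in% names(store)))
  onto_outcome <- store[store$outcome == outcome_id & store$pval < alpha, ]
  sig_traits <- unique(onto_outcome$exposure)
  links <- store[store$outcome != outcome_id &
                   store$exposure %in% sig_traits &
                   store$outcome %in% sig_traits &
                   store$pval < alpha, ]
  if (nrow(links) == 0) {
    return(data.frame(exposure = character(), mediator = character(),
                      outcome = character(), p_exp_out = numeric(),
                      p_med_out = numeric(), p_exp_med = numeric(),
                      stringsAsFactors = FALSE))
  }
  p_onto <- function(id) onto_outcome$pval[match(id, onto_outcome$exposure)]
  out <- data.frame(exposure = links$exposure, mediator = links$outcome,
                    outcome = outcome_id,
                    p_exp_out = p_onto(links$exposure),
                    p_med_out = p_onto(links$outcome),
                    p_exp_med = links$pval, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Serialize mediation results to a flat table
#'
#' @param results list of `mediation_result` objects.
#' @return data.frame, one row per triple.
#' @export
mediation_results_table <- function(results) {
  if (inherits(results, "mediation_result")) results <- list(results)
  out <- do.call(rbind, lapply(results, as.data.frame))
  rownames(out) <- NULL
  out
}
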