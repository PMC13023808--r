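# Orchestration of the four-step exposure -> mediator -> outcome design:
# (1) each exposure vs the outcome; (2) each mediator vs the outcome, with a
# reverse-direction MR check for mediators passing screening; (3) screened
# exposures vs screened mediators; (4) mediation screening and the two-step
# decomposition on qualifying triples.

#' Study-level configuration
#'
#' Layer-specific instrument thresholds default to the conventions for the
#' data shapes involved: genome-wide significance with lenient clumping
#' (p < 5e-8, r2 < 0.1) for the cis-acting exposure layer, a relaxed p-value
#' with strict clumping (p < 5e-6, r2 < 0.001) for the mediator layer, both
#' with a 10,000 kb window.
#'
#' @param p_exposure,clump_r2_exposure instrument thresholds for the exposure
#'   layer (steps 1 and 3).
#' @param p_mediator,clump_r2_mediator instrument thresholds for the mediator
#'   layer (step 2).
#' @param p_reverse instrument p-value threshold when the outcome is used as
#'   the exposure in the reverse-direction check (default 5e-8; clumped at the
#'   mediator-layer settings).
#' @param clump_window_kb clumping window in kb (both layers).
#' @param f_min weak-instrument F threshold (SNPs with F < f_min excluded).
#' @param steiger apply Steiger directionality filtering.
#' @param palindrome_band EAF ambiguity band for palindromic SNPs.
#' @param alpha screening significance level on the IVW p-value.
#' @param mt_mode multiple-testing annotation: `"none"`, `"bonferroni"` or
#'   `"bh"` (annotation only; screening always uses nominal `alpha`, with the
#'   implied corrected threshold reported).
#' @param n_boot bootstrap iterations for median/mode estimators.
#' @param presso_n_sim MR-PRESSO simulation count.
#' @param seed master seed; per-pair sub-seeds are derived deterministically
#'   from it and the pair labels, so adding a pair never perturbs the others.
#' @return A `study_config` list.
#' @export
study_config <- function(p_exposure = 5e-8, clump_r2_exposure = 0.1,
                         p_mediator = 5e-6, clump_r2_mediator = 0.001,
                         p_reverse = 5e-8, clump_window_kb = 10000,
                         f_min = 10, steiger = TRUE, palindrome_band = 0.08,
                         alpha = 0.05, mt_mode = c("none", "bonferroni", "bh"),
                         n_boot = 1000, presso_n_sim = 1000, seed = 1L) {
  mt_mode <- match.arg(mt_mode)
  stopifnot(p_exposure > 0, p_exposure < 1, p_mediator > 0, p_mediator < 1,
            clump_r2_exposure > 0, clump_r2_exposure <= 1,
            clump_r2_mediator > 0, clump_r2_mediator <= 1,
            clump_window_kb > 0, f_min >= 0, alpha > 0, alpha < 1,
            n_boot >= 1, presso_n_sim >= 1, !is.null(seed))
  structure(as.list(environment()), class = "study_config")
}

#' Run one exposure-outcome MR analysis with full quality control
#'
#' Applies the instrument QC chain — p-value selection, greedy LD clumping
#' (when an LD matrix is supplied), weak-instrument F filtering, allele
#' harmonization, Steiger directionality filtering — then the estimator
#' battery and the sensitivity report.
#'
#' @param exposure,outcome [gwas_table()]s.
#' @param ld optional [ld_matrix()] for clumping.
#' @param p_threshold,clump_r2,window_kb,f_min,steiger,palindrome_band QC
#'   settings (see [study_config()]).
#' @param n_boot,presso_n_sim,seed stochastic-component settings.
#' @param sensitivity compute the sensitivity battery (default TRUE).
#' @return An `mr_pair_result` list: `exposure`, `outcome`, `hset`,
#'   `results` (named `mr_result` list), `skipped`, `sensitivity`,
#'   `steiger_report`, `drop_log`, `ld_warning` (TRUE when `clump_r2 >= 0.1`,
#'   flagging that estimators assume independent instruments).
#' @export
mr_pair <- function(exposure, outcome, ld = NULL, p_threshold = 5e-8,
                    clump_r2 = 0.1, window_kb = 10000, f_min = 10,
                    steiger = TRUE, palindrome_band = 0.08, n_boot = 1000,
                    presso_n_sim = 1000, seed = NULL, sensitivity = TRUE) {
  sel <- select_instruments(exposure, p_threshold)
  if (nrow(sel) == 0) stopf("mr_pair: no instruments at p < %g for '%s'",
                            p_threshold, attr(exposure, "trait_id"))
  if (!is.null(ld)) sel <- clump(sel, ld, r2_max = clump_r2, window_kb = window_kb)
  sel <- filter_weak_instruments(sel, f_min = f_min)
  if (nrow(sel) == 0) stopf("mr_pair: all instruments weak (F < %g) for '%s'",
                            f_min, attr(exposure, "trait_id"))
  hset <- harmonize(sel, outcome, palindrome_eaf_band = palindrome_band)
  steiger_report <- NULL
  if (steiger) {
    st <- steiger_filter(hset)
    hset <- st$hset
    steiger_report <- st$report
    if (nrow(hset) == 0) stopf("mr_pair: no instruments survive Steiger filtering")
  }
  if (nrow(hset) == 1) {
    warnf("mr_pair: single instrument for '%s' -> '%s'; Wald ratio only",
          attr(exposure, "trait_id"), attr(outcome, "trait_id"))
  }
  battery <- mr_run_all(hset, n_boot = n_boot, seed = seed)
  sens <- if (sensitivity) {
    sensitivity_report(hset, results = battery$results, n_sim = presso_n_sim,
                       seed = seed)
  } else NULL
  structure(list(
    exposure = attr(exposure, "trait_id"), outcome = attr(outcome, "trait_id"),
    hset = hset, results = battery$results, skipped = battery$skipped,
    sensitivity = sens, steiger_report = steiger_report,
    drop_log = drop_log(hset), ld_warning = clump_r2 >= 0.1, seed = seed
  ), class = "mr_pair_result")
}

mt_annotate <- function(tab, alpha, mt_mode) {
  if (is.null(tab) || nrow(tab) == 0) return(tab)
  tab$pval_adj <- switch(mt_mode,
                         none = tab$pval,
                         bonferroni = stats::p.adjust(tab$pval, "bonferroni"),
                         bh = stats::p.adjust(tab$pval, "BH"))
  tab
}

step_summary <- function(tab, alpha, mt_mode) {
  if (is.null(tab) || nrow(tab) == 0) {
    return(list(n_tests = 0, expected_false_positives = 0,
                implied_threshold = alpha))
  }
  n <- nrow(tab)
  list(n_tests = n,
       expected_false_positives = n * alpha,
       implied_threshold = if (mt_mode == "bonferroni") alpha / n else alpha)
}

run_pair_safe <- function(label, aborted_env, ...) {
  tryCatch(mr_pair(...), error = function(e) {
    aborted_env$aborted <- rbind(aborted_env$aborted,
                                 data.frame(pair = label,
                                            message = conditionMessage(e),
                                            stringsAsFactors = FALSE))
    NULL
  })
}

# one screening row per pair: the IVW result (a Wald ratio for single-SNP pairs)
ivw_row <- function(pair) {
  if (is.null(pair)) return(NULL)
  as.data.frame(pair$results$ivw)
}

#' Run the full four-step mediation study
#'
#' @param exposures named list of exposure [gwas_table()]s.
#' @param mediators named list of mediator [gwas_table()]s.
#' @param outcome the outcome [gwas_table()].
#' @param ld optional [ld_matrix()] used for clumping in every layer.
#' @param config a [study_config()].
#' @return A `study_report` list: per-step result tables (`step1`, `step2`,
#'   `step2_reverse`, `step3` — IVW/Wald rows with multiple-testing
#'   annotation), full per-pair objects (`pairs`), the mediation table
#'   (`mediation`) and triple list, step summaries with expected-false-positive
#'   arithmetic, aborted pairs, drop logs, the config echo, the master seed
#'   and package version.
#' @export
run_study <- function(exposures, mediators, outcome, ld = NULL,
                      config = study_config()) {
  stopifnot(inherits(config, "study_config"), inherits(outcome, "gwas_table"))
  if (is.null(names(exposures)) || is.null(names(mediators))) {
    exposures <- stats::setNames(exposures, vapply(exposures, attr, "",
                                                   "trait_id"))
    mediators <- stats::setNames(mediators, vapply(mediators, attr, "",
                                                   "trait_id"))
  }
  outcome_id <- attr(outcome, "trait_id")
  ab <- new.env()
  ab$aborted <- data.frame(pair = character(), message = character(),
                           stringsAsFactors = FALSE)
  pair_seed <- function(a, b) derive_seed(config$seed, paste0(a, "->", b))
  pairs <- list()

  # step 1: exposures vs outcome at exposure-layer thresholds
  step1_pairs <- lapply(names(exposures), function(id) {
    run_pair_safe(paste0(id, "->", outcome_id), ab,
                  exposures[[id]], outcome, ld = ld,
                  p_threshold = config$p_exposure,
                  clump_r2 = config$clump_r2_exposure,
                  window_kb = config$clump_window_kb, f_min = config$f_min,
                  steiger = config$steiger,
                  palindrome_band = config$palindrome_band,
                  n_boot = config$n_boot, presso_n_sim = config$presso_n_sim,
                  seed = pair_seed(id, outcome_id))
  })
  names(step1_pairs) <- names(exposures)
  step1 <- do.call(rbind, lapply(step1_pairs, ivw_row))
  pairs[paste0(names(exposures), "->", outcome_id)] <- step1_pairs

  # step 2: mediators vs outcome at mediator-layer thresholds
  step2_pairs <- lapply(names(mediators), function(id) {
    run_pair_safe(paste0(id, "->", outcome_id), ab,
                  mediators[[id]], outcome, ld = ld,
                  p_threshold = config$p_mediator,
                  clump_r2 = config$clump_r2_mediator,
                  window_kb = config$clump_window_kb, f_min = config$f_min,
                  steiger = config$steiger,
                  palindrome_band = config$palindrome_band,
                  n_boot = config$n_boot, presso_n_sim = config$presso_n_sim,
                  seed = pair_seed(id, outcome_id))
  })
  names(step2_pairs) <- names(mediators)
  step2 <- do.call(rbind, lapply(step2_pairs, ivw_row))
  pairs[paste0(names(mediators), "->", outcome_id)] <- step2_pairs

  sig_exposures <- if (!is.null(step1)) step1$exposure[step1$pval < config$alpha]
    else character(0)
  sig_mediators <- if (!is.null(step2)) step2$exposure[step2$pval < config$alpha]
    else character(0)

  # reverse check: outcome as exposure for each screened mediator; significant
  # reverse pairs are annotated, never excluded
  step2_reverse <- NULL
  for (id in sig_mediators) {
    rp <- run_pair_safe(paste0(outcome_id, "->", id), ab,
                        outcome, mediators[[id]], ld = ld,
                        p_threshold = config$p_reverse,
                        clump_r2 = config$clump_r2_mediator,
                        window_kb = config$clump_window_kb,
                        f_min = config$f_min, steiger = config$steiger,
                        palindrome_band = config$palindrome_band,
                        n_boot = config$n_boot,
                        presso_n_sim = config$presso_n_sim,
                        seed = pair_seed(outcome_id, id), sensitivity = FALSE)
    if (!is.null(rp)) {
      row <- ivw_row(rp)
      row$reverse_significant <- row$pval < config$alpha
      step2_reverse <- rbind(step2_reverse, row)
      pairs[[paste0(outcome_id, "->", id)]] <- rp
    }
  }

  # step 3: screened exposures vs screened mediators at exposure thresholds
  step3 <- NULL
  step3_pairs <- list()
  for (eid in sig_exposures) {
    for (mid in sig_mediators) {
      pr <- run_pair_safe(paste0(eid, "->", mid), ab,
                          exposures[[eid]], mediators[[mid]], ld = ld,
                          p_threshold = config$p_exposure,
                          clump_r2 = config$clump_r2_exposure,
                          window_kb = config$clump_window_kb,
                          f_min = config$f_min, steiger = config$steiger,
                          palindrome_band = config$palindrome_band,
                          n_boot = config$n_boot,
                          presso_n_sim = config$presso_n_sim,
                          seed = pair_seed(eid, mid), sensitivity = FALSE)
      if (!is.null(pr)) {
        step3 <- rbind(step3, ivw_row(pr))
        step3_pairs[[paste0(eid, "->", mid)]] <- pr
      }
    }
  }

  # step 4: mediation on qualifying triples
  store <- rbind(step1, step2, step3)
  triples <- if (!is.null(store)) {
    mediation_screen(store, outcome_id, alpha = config$alpha)
  } else {
    mediation_screen(data.frame(exposure = character(), outcome = character(),
                                pval = numeric()), outcome_id, config$alpha)
  }
  mediation_results <- lapply(seq_len(nrow(triples)), function(i) {
    eid <- triples$exposure[i]; mid <- triples$mediator[i]
    two_step_mediation(step1_pairs[[eid]]$results$ivw,
                       step3_pairs[[paste0(eid, "->", mid)]]$results$ivw,
                       step2_pairs[[mid]]$results$ivw)
  })
  mediation <- if (length(mediation_results) > 0) {
    mediation_results_table(mediation_results)
  } else NULL

  pairs <- c(pairs, step3_pairs)
  drop_logs <- do.call(rbind, lapply(names(pairs), function(nm) {
    p <- pairs[[nm]]
    if (is.null(p) || nrow(p$drop_log) == 0) return(NULL)
    cbind(pair = nm, p$drop_log)
  }))

  structure(list(
    step1 = mt_annotate(step1, config$alpha, config$mt_mode),
    step2 = mt_annotate(step2, config$alpha, config$mt_mode),
    step2_reverse = step2_reverse,
    step3 = mt_annotate(step3, config$alpha, config$mt_mode),
    mediation = mediation, triples = triples,
    mediation_results = mediation_results,
    screened_exposures = sig_exposures, screened_mediators = sig_mediators,
    summaries = list(step1 = step_summary(step1, config$alpha, config$mt_mode),
                     step2 = step_summary(step2, config$alpha, config$mt_mode),
                     step3 = step_summary(step3, config$alpha, config$mt_mode)),
    pairs = pairs, aborted = ab$aborted, drop_logs = drop_logs,
    config = unclass(config), seed = config$seed,
    version = as.character(utils::packageVersion("mrchain"))
  ), class = "study_report")
}

#' Convenience accessor: the GWAS tables of a synthetic study as run_study inputs
#'
#' @param study a [simulate_chain()] result.
#' @return list(exposures, mediators, outcome, ld) suitable for [run_study()].
#' @export
study_inputs <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  list(exposures = list(exposure = study$exposure_gwas),
       mediators = list(mediator = study$mediator_gwas),
       outcome = study$outcome_gwas, ld = study$ld)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> seed %s, version %s\n", x$seed, x$version))
  for (s in c("step1", "step2", "step3")) {
    t <- x[[s]]
    cat(sprintf("  %s: %d pair(s), expected false positives %.2f\n", s,
                x$summaries[[s]]$n_tests,
                x$summaries[[s]]$expected_false_positives))
  }
  cat(sprintf("  mediation: %d qualifying triple(s); %d aborted pair(s)\n",
              nrow(x$triples), nrow(x$aborted)))
  invisible(x)
}

write_tsv <- function(tab, path) {
  if (is.null(tab)) tab <- data.frame()
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a study report as a JSON + TSV bundle
#'
#' Output is deterministic: the same report writes byte-identical files.
#'
#' @param report a [run_study()] report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(report$step1, file.path(dir, "step1_exposure_outcome.tsv"))
  write_tsv(report$step2, file.path(dir, "step2_mediator_outcome.tsv"))
  write_tsv(report$step2_reverse, file.path(dir, "step2_reverse_mr.tsv"))
  write_tsv(report$step3, file.path(dir, "step3_exposure_mediator.tsv"))
  write_tsv(report$mediation, file.path(dir, "step4_mediation.tsv"))
  write_tsv(report$drop_logs, file.path(dir, "drop_log.tsv"))
  write_tsv(report$aborted, file.path(dir, "aborted_pairs.tsv"))
  jsonlite::write_json(
    list(config = report$config, seed = report$seed, version = report$version,
         screened_exposures = report$screened_exposures,
         screened_mediators = report$screened_mediators,
         summaries = report$summaries),
    file.path(dir, "study.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a study configuration from YAML
#'
#' Recognized keys are the arguments of [study_config()]; unknown keys are an
#' error.
#'
#' @param path YAML file path.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(study_config)))
  if (length(unknown) > 0) {
    stopf("read_study_config: unknown key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(study_config, vals)
}
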