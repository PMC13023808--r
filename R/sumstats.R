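# GWAS summary-statistics containers, IO, and instrument quality control.
#
# A `gwas_table` is a validated data.frame of per-SNP marginal associations for
# one trait; a `harmonized_set` holds allele-aligned exposure/outcome effect
# pairs ready for the MR estimators. Every record excluded along the way is
# written to a drop log (snp_id, stage, reason) carried on the object.

CANONICAL_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pval", "n", "n_cases")
MANDATORY_COLS <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")
CANONICAL_HEADER <- c(SNP = "snp_id", CHR = "chrom", POS = "pos",
                      EA = "effect_allele", OA = "other_allele", EAF = "eaf",
                      BETA = "beta", SE = "se", P = "pval", N = "n",
                      N_CASES = "n_cases")

#' Construct a validated GWAS summary-statistics table
#'
#' Coerces a data.frame of per-SNP associations into a `gwas_table`, enforcing
#' the record invariants (distinct A/C/G/T alleles, positive standard error,
#' p-value in (0, 1], allele frequency in \[0, 1\] when present). Rows failing
#' an invariant are dropped and logged with a reason code rather than raising;
#' duplicated SNP identifiers keep the smallest-p record. Row order of the
#' surviving records is preserved.
#'
#' @param df data.frame with (a subset of) the canonical columns `snp_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pval`, `n`, `n_cases`.
#' @param trait_id trait label.
#' @param trait_type `"quantitative"` or `"binary"`. Binary traits require a
#'   case count, either per record (`n_cases` column) or via `n_cases`.
#' @param provenance free-text source note.
#' @param n_cases table-level case count for binary traits (optional).
#' @return A `gwas_table`: the validated data.frame with attributes
#'   `trait_id`, `trait_type`, `provenance` and a `drop_log` data.frame.
#' @export
gwas_table <- function(df, trait_id, trait_type = c("quantitative", "binary"),
                       provenance = "", n_cases = NULL) {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(MANDATORY_COLS, names(df))
  if (length(missing_cols) > 0) {
    stopf("gwas_table '%s': missing mandatory column(s): %s",
          trait_id, paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(CANONICAL_COLS, names(df))) df[[col]] <- NA
  df <- df[, CANONICAL_COLS]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n", "n_cases")) {
    df[[col]] <- as.numeric(df[[col]])
  }

  log <- empty_drop_log()
  flag <- function(bad, reason) {
    bad[is.na(bad)] <- FALSE
    log <<- add_drops(log, df$snp_id[bad & keep], "validate", reason)
    keep <<- keep & !bad
  }
  keep <- rep(TRUE, nrow(df))
  flag(is.na(df$beta) | is.na(df$se) | is.na(df$pval) | is.na(df$snp_id) |
         df$snp_id == "", "missing_required_value")
  flag(!(df$effect_allele %in% c("A", "C", "G", "T")) |
         !(df$other_allele %in% c("A", "C", "G", "T")), "invalid_alleles")
  flag(df$effect_allele == df$other_allele, "same_alleles")
  flag(df$se <= 0, "nonpositive_se")
  flag(df$pval <= 0 | df$pval > 1, "invalid_pval")
  flag(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "invalid_eaf")

  df <- df[keep, , drop = FALSE]
  # duplicate snp_id: keep smallest p, log the rest
  if (anyDuplicated(df$snp_id)) {
    ord <- order(df$pval)
    dup <- ord[duplicated(df$snp_id[ord])]
    log <- add_drops(log, df$snp_id[dup], "validate", "duplicate_snp_id")
    df <- df[sort(setdiff(seq_len(nrow(df)), dup)), , drop = FALSE]
  }
  if (nrow(df) == 0) stopf("gwas_table '%s': no records survive validation", trait_id)
  if (trait_type == "binary" && all(is.na(df$n_cases)) && is.null(n_cases)) {
    stopf("gwas_table '%s': binary trait requires n_cases (column or argument)",
          trait_id)
  }
  if (!is.null(n_cases) && all(is.na(df$n_cases))) df$n_cases <- n_cases
  rownames(df) <- NULL
  structure(df, class = c("gwas_table", "data.frame"),
            trait_id = trait_id, trait_type = trait_type,
            provenance = provenance, drop_log = log)
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("<gwas_table> trait '%s' (%s): %d SNPs, %d dropped in validation\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x),
              nrow(attr(x, "drop_log"))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Read a GWAS summary-statistics file into a `gwas_table`
#'
#' Reads a delimited text file (tab, comma or whitespace separated; header
#' required). The canonical header is `SNP CHR POS EA OA EAF BETA SE P N
#' N_CASES`; other spellings are accepted through `dialect`, a named character
#' vector mapping source column names to canonical field names (either the
#' canonical header tokens or the internal names, e.g. `c(rsid = "SNP",
#' a1 = "effect_allele")`).
#'
#' @inheritParams gwas_table
#' @param path file path.
#' @param dialect named character vector: names are source columns, values
#'   canonical names. Unmapped columns matching the canonical header are used
#'   as-is; others are ignored.
#' @param sep field separator; `""` (default) auto-detects tab/comma/whitespace.
#' @return A validated [gwas_table()].
#' @export
read_gwas_table <- function(path, trait_id = basename(path),
                            trait_type = c("quantitative", "binary"),
                            dialect = NULL, provenance = path, n_cases = NULL,
                            sep = "") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stopf("read_gwas_table: no such file: %s", path)
  if (identical(sep, "")) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  nm <- names(raw)
  if (!is.null(dialect)) {
    hit <- nm %in% names(dialect)
    nm[hit] <- unname(dialect[nm[hit]])
  }
  # accept both canonical-header tokens and internal names
  hit <- toupper(nm) %in% names(CANONICAL_HEADER)
  nm[hit] <- unname(CANONICAL_HEADER[toupper(nm[hit])])
  names(raw) <- nm
  raw <- raw[, nm %in% CANONICAL_COLS, drop = FALSE]
  missing_cols <- setdiff(MANDATORY_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stopf("read_gwas_table '%s': missing mandatory column(s): %s (check dialect mapping)",
          path, paste(missing_cols, collapse = ", "))
  }
  gwas_table(raw, trait_id = trait_id, trait_type = trait_type,
             provenance = provenance, n_cases = n_cases)
}

#' Write a `gwas_table` to the canonical TSV layout
#'
#' @param table a [gwas_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(table, path) {
  out <- as.data.frame(table)[, CANONICAL_COLS]
  names(out) <- names(CANONICAL_HEADER)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated LD matrix
#'
#' @param r2 square numeric matrix of squared correlations in \[0, 1\],
#'   symmetric (tolerance 1e-12) with unit diagonal.
#' @param snp_ids SNP labels; defaults to the matrix dimnames.
#' @return An `ld_matrix` (a plain matrix with validated structure).
#' @export
ld_matrix <- function(r2, snp_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(snp_ids)) stopf("ld_matrix: snp_ids required")
  if (nrow(r2) != ncol(r2) || nrow(r2) != length(snp_ids)) {
    stopf("ld_matrix: dimensions (%d x %d) do not match %d snp_ids",
          nrow(r2), ncol(r2), length(snp_ids))
  }
  if (max(abs(r2 - t(r2))) > 1e-12) stopf("ld_matrix: matrix not symmetric")
  if (any(abs(diag(r2) - 1) > 1e-12)) stopf("ld_matrix: diagonal must be 1")
  if (any(r2 < 0 | r2 > 1 + 1e-12)) stopf("ld_matrix: r2 outside [0, 1]")
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(r2, class = c("ld_matrix", "matrix", "array"))
}

#' Read an LD matrix file
#'
#' Accepts either a square whitespace/tab-delimited matrix with a header row of
#' SNP IDs, or a long-format 3-column file (`snp_a`, `snp_b`, `r2`); unlisted
#' pairs in long format default to r2 = 0.
#'
#' @param path file path.
#' @return An [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(raw) == 3 && !is.numeric(raw[[1]])) {
    ids <- unique(c(as.character(raw[[1]]), as.character(raw[[2]])))
    m <- diag(length(ids))
    dimnames(m) <- list(ids, ids)
    ia <- match(as.character(raw[[1]]), ids)
    ib <- match(as.character(raw[[2]]), ids)
    m[cbind(ia, ib)] <- raw[[3]]
    m[cbind(ib, ia)] <- raw[[3]]
    diag(m) <- 1
    return(ld_matrix(m))
  }
  m <- as.matrix(raw)
  rownames(m) <- colnames(m)
  ld_matrix(m)
}

drop_log <- function(x) attr(x, "drop_log") %||% empty_drop_log()

set_records <- function(table, keep_idx, extra_log = NULL) {
  out <- as.data.frame(table)[keep_idx, , drop = FALSE]
  rownames(out) <- NULL
  log <- drop_log(table)
  if (!is.null(extra_log)) log <- rbind(log, extra_log)
  structure(out, class = class(table), trait_id = attr(table, "trait_id"),
            trait_type = attr(table, "trait_type"),
            provenance = attr(table, "provenance"), drop_log = log)
}

#' Select genome-wide instruments by p-value threshold
#'
#' Retains exactly the records with `pval < p_threshold` (strict inequality, so
#' a p-value equal to the threshold is excluded). Typical thresholds are
#' 5e-8 for eQTL exposures and 5e-6 for microbiome abundance traits.
#'
#' @param table a [gwas_table()].
#' @param p_threshold significance threshold in (0, 1).
#' @return The filtered `gwas_table`; empty selection yields a zero-row table
#'   with a warning (the caller decides whether that is fatal).
#' @export
select_instruments <- function(table, p_threshold = 5e-8) {
  stopifnot(inherits(table, "gwas_table"))
  if (!(p_threshold > 0 && p_threshold < 1)) {
    stopf("select_instruments: p_threshold must be in (0, 1)")
  }
  keep <- table$pval < p_threshold
  log <- add_drops(empty_drop_log(), table$snp_id[!keep], "select_instruments",
                   "above_p_threshold")
  if (!any(keep)) {
    warnf("select_instruments: no SNP passes p < %g for trait '%s'",
          p_threshold, attr(table, "trait_id"))
  }
  set_records(table, which(keep), log)
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the smallest-p remaining SNP (the index) and removes every
#' remaining SNP on the same chromosome within `window_kb` of it (center-to-
#' center) whose squared correlation with it is `>= r2_max`. SNPs absent from
#' the LD matrix are treated as unlinked and logged with a warning. Output is
#' ordered by p-value; no retained pair within the window violates the
#' threshold.
#'
#' @param table a [gwas_table()] with `chrom` and `pos` filled in.
#' @param ld an [ld_matrix()] covering (a superset of) the table's SNPs.
#' @param r2_max clumping threshold in (0, 1\]; e.g. 0.1 for cis-eQTL
#'   instruments, 0.001 for microbiome instruments.
#' @param window_kb clumping window in kb (e.g. 10000).
#' @return The clumped `gwas_table`, ordered by p-value.
#' @export
clump <- function(table, ld, r2_max = 0.001, window_kb = 10000) {
  stopifnot(inherits(table, "gwas_table"))
  if (!(window_kb > 0)) stopf("clump: window_kb must be > 0")
  if (!(r2_max > 0 && r2_max <= 1)) stopf("clump: r2_max must be in (0, 1]")
  if (nrow(table) == 0) return(table)
  in_ld <- table$snp_id %in% rownames(ld)
  log <- empty_drop_log()
  if (any(!in_ld)) {
    warnf("clump: %d SNP(s) absent from LD matrix; treated as unlinked",
          sum(!in_ld))
    # informational: these SNPs stay in the table but could not be checked
    log <- add_drops(log, table$snp_id[!in_ld], "clump", "missing_from_ld_unlinked")
  }
  ord <- order(table$pval)
  alive <- rep(TRUE, nrow(table))
  kept <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    kept <- c(kept, i)
    alive[i] <- FALSE
    cand <- which(alive & table$chrom == table$chrom[i] &
                    abs(table$pos - table$pos[i]) <= window_kb * 1000)
    if (length(cand) == 0) next
    r2 <- rep(0, length(cand))
    if (in_ld[i]) {
      have <- in_ld[cand]
      r2[have] <- ld[table$snp_id[i], table$snp_id[cand[have]]]
    }
    prune <- cand[r2 >= r2_max]
    if (length(prune) > 0) {
      log <- add_drops(log, table$snp_id[prune], "clump", "ld_with_index_snp")
      alive[prune] <- FALSE
    }
  }
  set_records(table, kept, log)
}

#' Approximate per-SNP instrument F-statistic
#'
#' Computed as `(beta / se)^2`, the square of the marginal Z-score; F < 10 is
#' the conventional weak-instrument flag.
#'
#' @param beta per-allele effect estimate(s).
#' @param se standard error(s), > 0.
#' @return Numeric vector of F-statistics.
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0, na.rm = TRUE)) stopf("f_statistic: se must be > 0")
  (beta / se)^2
}

#' Drop weak instruments by F-statistic
#'
#' Removes records with `f_statistic(beta, se) < f_min` (strict: F exactly at
#' the threshold is retained), logging reason `"weak_instrument"`.
#'
#' @param table a [gwas_table()].
#' @param f_min weak-instrument threshold (default 10).
#' @return The filtered `gwas_table`.
#' @export
filter_weak_instruments <- function(table, f_min = 10) {
  stopifnot(inherits(table, "gwas_table"))
  f <- f_statistic(table$beta, table$se)
  keep <- f >= f_min
  log <- add_drops(empty_drop_log(), table$snp_id[!keep], "f_filter",
                   "weak_instrument")
  set_records(table, which(keep), log)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

complement_allele <- function(a) c(A = "T", T = "A", C = "G", G = "C")[a]

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome effects to the exposure's effect allele for every SNP
#' shared by the two tables. Same allele pair in the same orientation: copied
#' unchanged. Swapped alleles: outcome beta negated and outcome EAF replaced by
#' 1 - EAF. Alleles matching only after strand complementation are treated the
#' same way. Palindromic pairs (A/T, G/C), whose orientation cannot be read
#' from the alleles, are resolved by comparing the allele frequency to 1/2 in
#' both studies; the SNP is dropped (`"ambiguous_palindrome"`) when either EAF
#' is missing or within `palindrome_eaf_band` of 1/2. Allele pairs compatible
#' under no orientation are dropped (`"incompatible_alleles"`). Every drop is
#' logged.
#'
#' @param exp,out exposure and outcome [gwas_table()]s.
#' @param palindrome_eaf_band half-width of the ambiguity band around EAF = 0.5
#'   (default 0.08).
#' @param n_exp,n_out sample-size overrides; default to the per-record medians.
#' @return A `harmonized_set`: data.frame with columns `snp_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `beta_exp`, `se_exp`, `pval_exp`,
#'   `eaf`, `beta_out`, `se_out`, `pval_out`, plus attributes `exposure_id`,
#'   `outcome_id`, `n_exp`, `n_out`, `n_cases_out`, `outcome_type`, `drop_log`.
#' @export
harmonize <- function(exp, out, palindrome_eaf_band = 0.08,
                      n_exp = NULL, n_out = NULL) {
  stopifnot(inherits(exp, "gwas_table"), inherits(out, "gwas_table"))
  shared <- intersect(exp$snp_id, out$snp_id)
  if (length(shared) == 0) {
    stopf("harmonize: no shared SNPs between exposure '%s' and outcome '%s'",
          attr(exp, "trait_id"), attr(out, "trait_id"))
  }
  e <- as.data.frame(exp)[match(shared, exp$snp_id), ]
  o <- as.data.frame(out)[match(shared, out$snp_id), ]

  log <- empty_drop_log()
  log <- add_drops(log, setdiff(exp$snp_id, shared), "harmonize", "absent_in_outcome")

  same <- e$effect_allele == o$effect_allele & e$other_allele == o$other_allele
  swap <- e$effect_allele == o$other_allele & e$other_allele == o$effect_allele
  flip_ea <- complement_allele(o$effect_allele)
  flip_oa <- complement_allele(o$other_allele)
  same_c <- e$effect_allele == flip_ea & e$other_allele == flip_oa
  swap_c <- e$effect_allele == flip_oa & e$other_allele == flip_ea
  pal <- is_palindromic(e$effect_allele, e$other_allele)

  keep <- rep(TRUE, length(shared))
  action <- rep("copy", length(shared))
  action[(swap | swap_c) & !pal] <- "flip"
  incompatible <- !(same | swap | same_c | swap_c)
  keep[incompatible] <- FALSE
  log <- add_drops(log, shared[incompatible], "harmonize", "incompatible_alleles")

  # palindromic: alleles carry no orientation signal; infer from EAF
  if (any(pal & keep)) {
    idx <- which(pal & keep)
    ambiguous <- is.na(e$eaf[idx]) | is.na(o$eaf[idx]) |
      abs(e$eaf[idx] - 0.5) < palindrome_eaf_band |
      abs(o$eaf[idx] - 0.5) < palindrome_eaf_band
    log <- add_drops(log, shared[idx[ambiguous]], "harmonize", "ambiguous_palindrome")
    keep[idx[ambiguous]] <- FALSE
    ok <- idx[!ambiguous]
    opposite <- sign(e$eaf[ok] - 0.5) != sign(o$eaf[ok] - 0.5)
    action[ok] <- ifelse(opposite, "flip", "copy")
  }

  beta_out <- ifelse(action == "flip", -o$beta, o$beta)
  eaf_out <- ifelse(action == "flip", 1 - o$eaf, o$eaf)

  h <- data.frame(
    snp_id = shared, chrom = e$chrom, pos = e$pos,
    effect_allele = e$effect_allele, other_allele = e$other_allele,
    beta_exp = e$beta, se_exp = e$se, pval_exp = e$pval, eaf = e$eaf,
    beta_out = beta_out, se_out = o$se, pval_out = o$pval, eaf_out = eaf_out,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(h) <- NULL
  if (nrow(h) == 0) {
    stopf("harmonize: no SNPs survive allele harmonization for '%s' vs '%s'",
          attr(exp, "trait_id"), attr(out, "trait_id"))
  }
  structure(h, class = c("harmonized_set", "data.frame"),
            exposure_id = attr(exp, "trait_id"),
            outcome_id = attr(out, "trait_id"),
            outcome_type = attr(out, "trait_type"),
            n_exp = n_exp %||% stats::median(exp$n, na.rm = TRUE),
            n_out = n_out %||% stats::median(out$n, na.rm = TRUE),
            n_cases_out = if (all(is.na(out$n_cases))) NULL else
              stats::median(out$n_cases, na.rm = TRUE),
            drop_log = rbind(drop_log(exp), drop_log(out), log))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d instruments\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"), nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

subset_hset <- function(hset, idx, extra_log = NULL) {
  out <- as.data.frame(hset)[idx, , drop = FALSE]
  rownames(out) <- NULL
  at <- attributes(hset)
  structure(out, class = class(hset), exposure_id = at$exposure_id,
            outcome_id = at$outcome_id, outcome_type = at$outcome_type,
            n_exp = at$n_exp, n_out = at$n_out, n_cases_out = at$n_cases_out,
            drop_log = rbind(drop_log(hset), extra_log))
}

#' Steiger directionality filter
#'
#' For each instrument, the variance explained in each trait is approximated
#' from the marginal Z-score as r2 = Z^2 / (Z^2 + n); SNPs explaining more
#' variance in the outcome than in the exposure (r2_out > r2_exp) are likely
#' reverse-direction instruments and are removed. For binary outcomes this r2
#' is an observed-scale approximation (flagged in the report). A per-SNP
#' Steiger test p-value compares the two implied correlations by Fisher's
#' z-transformation.
#'
#' @param hset a [harmonize()]d instrument set with known sample sizes.
#' @return A list with elements `hset` (the filtered set, drops logged with
#'   reason `"steiger_reverse"`) and `report` (per-SNP data.frame with
#'   `r2_exp`, `r2_out`, `direction_ok`, `steiger_z`, `steiger_p`,
#'   `binary_outcome_approx`).
#' @export
steiger_filter <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  n_exp <- attr(hset, "n_exp")
  n_out <- attr(hset, "n_out")
  if (is.na(n_exp) || is.na(n_out) || n_exp <= 2 || n_out <= 2) {
    stopf("steiger_filter: sample sizes must be known and > 2")
  }
  z_exp <- hset$beta_exp / hset$se_exp
  z_out <- hset$beta_out / hset$se_out
  r2_exp <- z_exp^2 / (z_exp^2 + n_exp)
  r2_out <- z_out^2 / (z_out^2 + n_out)
  ok <- !(r2_out > r2_exp)
  # Fisher z two-correlation comparison; needs n > 3 in both studies
  if (n_exp > 3 && n_out > 3) {
    zdiff <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
      sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
    steiger_p <- 2 * stats::pnorm(-abs(zdiff))
  } else {
    zdiff <- rep(NA_real_, nrow(hset))
    steiger_p <- rep(NA_real_, nrow(hset))
  }
  report <- data.frame(
    snp_id = hset$snp_id, r2_exp = r2_exp, r2_out = r2_out,
    direction_ok = ok, steiger_z = zdiff, steiger_p = steiger_p,
    binary_outcome_approx = identical(attr(hset, "outcome_type"), "binary"),
    stringsAsFactors = FALSE
  )
  log <- add_drops(empty_drop_log(), hset$snp_id[!ok], "steiger", "steiger_reverse")
  list(hset = subset_hset(hset, which(ok), log), report = report)
}
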