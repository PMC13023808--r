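# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded estimator internals
#' (bootstraps, MR-PRESSO simulations) never perturb the caller's RNG stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministic 31-bit hash of a label, used to derive per-pair sub-seeds from
# a master seed so that adding one analysis pair never perturbs another.
hash_label <- function(label) {
  codes <- utf8ToInt(paste(label, collapse = "|"))
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

#' Derive a deterministic sub-seed from a master seed and a label
#'
#' @param master_seed integer master seed.
#' @param label character label (e.g. "exposure1::outcome").
#' @return an integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(master_seed, label) {
  as.integer((as.numeric(master_seed) %% 2147483647 + hash_label(label)) %% 2147483647)
}

# Empty drop-log skeleton; every QC stage appends rows (snp_id, stage, reason).
empty_drop_log <- function() {
  data.frame(snp_id = character(), stage = character(), reason = character(),
             stringsAsFactors = FALSE)
}

add_drops <- function(log, snp_id, stage, reason) {
  if (length(snp_id) == 0) return(log)
  rbind(log, data.frame(snp_id = as.character(snp_id), stage = stage,
                        reason = reason, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
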