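# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("arousalpha_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_degenerate <- function(...) {
  stop(structure(class = c("arousalpha_degenerate_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop_invalid(msg)

#' Derive a child seed from a parent seed and a counter
#'
#' Counter-based fan-out so that one cohort-level seed yields
#' non-colliding, reproducible per-subject and per-permutation seeds.
#' Kept below 2^31 so the result is a valid R integer.
#'
#' @param seed parent integer seed
#' @param counter non-negative integer stream index
#' @return integer seed
#' @export
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 69621) %% 2147483647)
}

# Tie-corrected Mann-Whitney ROC-AUC. `scores` oriented so that larger
# values indicate the positive class. Used in permutation loops where a
# heavier AUC routine's per-call overhead would dominate; agreement with
# pROC::auc is covered by a unit test.
auc_rank <- function(labels_pos, scores) {
  n_pos <- sum(labels_pos)
  n_neg <- sum(!labels_pos)
  if (n_pos == 0L || n_neg == 0L)
    stop_invalid("AUC needs both classes present in the test set")
  r <- rank(scores)
  (sum(r[labels_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Permutation p-value with the +1 correction (avoids p = 0).
perm_pvalue <- function(n_extreme, n_perm) (n_extreme + 1) / (n_perm + 1)
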