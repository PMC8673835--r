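# Subject-level and group-level statistics, model comparison, and the
# break-exclusion control.

#' Exact binomial test against chance-level decoding
#'
#' Exact tail summation of the binomial pmf (no normal approximation),
#' comparing the number of correct predictions to a null classifier with
#' accuracy `p0`.
#'
#' @param n_correct number of correct predictions
#' @param n_total number of predictions (180 retained epochs by default)
#' @param p0 null accuracy
#' @param sided "two" (default) or "greater"
#' @return p-value
#' @export
exact_binomial_test <- function(n_correct, n_total = 180, p0 = 0.5,
                                sided = c("two", "greater")) {
  assert_that(n_correct >= 0 && n_correct <= n_total,
              "n_correct must lie in [0, n_total]")
  sided <- match.arg(sided)
  alt <- if (sided == "two") "two.sided" else "greater"
  stats::binom.test(n_correct, n_total, p = p0, alternative = alt)$p.value
}

#' Group-level mean test against a chance benchmark
#'
#' One-sided (upper-tail) one-sample t-test of per-subject accuracies
#' against the theoretical accuracy of a random classifier.
#'
#' @param metrics per-subject metric values
#' @param mu0 benchmark value (0.5 for binary accuracy)
#' @return list with `t`, `df`, `p`
#' @export
group_mean_test <- function(metrics, mu0 = 0.5) {
  assert_that(length(metrics) >= 3, "need at least 3 subjects")
  if (stats::sd(metrics) == 0)
    stop_degenerate("zero variance across subjects: t undefined")
  ht <- stats::t.test(metrics, mu = mu0, alternative = "greater")
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Two-by-two repeated-measures ANOVA on accuracy scores
#'
#' Standard within-subject decomposition (model x condition, both within),
#' each effect tested with F(1, n-1). Only subjects present in both
#' conditions enter.
#'
#' @param acc numeric array `subjects x 2 (models) x 2 (conditions)`, or a
#'   data.frame with columns subject, model, condition, accuracy
#' @return data.frame with rows model, condition, interaction and columns
#'   `F`, `df1`, `df2`, `p`
#' @export
rm_anova_2x2 <- function(acc) {
  if (is.array(acc) && length(dim(acc)) == 3) {
    dn <- dimnames(acc) %||% list(NULL, c("m1", "m2"), c("c1", "c2"))
    df <- expand.grid(subject = seq_len(dim(acc)[1]),
                      model = dn[[2]] %||% c("m1", "m2"),
                      condition = dn[[3]] %||% c("c1", "c2"))
    df$accuracy <- as.vector(acc)
  } else {
    df <- as.data.frame(acc)
  }
  df <- df[stats::complete.cases(df), ]
  df$subject <- factor(df$subject)
  df$model <- factor(df$model)
  df$condition <- factor(df$condition)
  n <- nlevels(df$subject)
  if (n < 2) stop_invalid("need at least 2 complete subjects")
  fit <- stats::aov(accuracy ~ model * condition +
                      Error(subject / (model * condition)), data = df)
  s <- summary(fit)
  pick <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    i <- grep(term, trimws(rownames(tab)))
    f <- tab[i, "F value"]; p <- tab[i, "Pr(>F)"]
    if (!is.finite(f) || tab[i, "Sum Sq"] < 1e-12) { f <- 0; p <- 1 }
    c(F = f, df1 = tab[i, "Df"], df2 = tab[nrow(tab), "Df"], p = p)
  }
  out <- rbind(model = pick("Error: subject:model", "^model$"),
               condition = pick("Error: subject:condition", "^condition$"),
               interaction = pick("Error: subject:model:condition",
                                  "model:condition"))
  as.data.frame(out)
}

#' Paired comparison of decoding metrics
#'
#' Two-sided paired t-test, e.g. performance with vs without the break.
#'
#' @param metric_with,metric_without paired per-subject metric vectors
#' @return list with `t`, `df`, `p`
#' @export
paired_comparison <- function(metric_with, metric_without) {
  assert_that(length(metric_with) == length(metric_without),
              "paired vectors must have equal length")
  assert_that(length(metric_with) >= 3, "need at least 3 pairs")
  d <- metric_with - metric_without
  if (all(d == 0))
    return(list(t = 0, df = length(d) - 1, p = 1))
  if (stats::sd(d) == 0)
    stop_degenerate("zero-variance differences: paired t undefined")
  ht <- stats::t.test(metric_with, metric_without, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Cross-model performance correlations with Bonferroni correction
#'
#' Pairwise Pearson correlations between per-subject metrics of different
#' models; p-values are multiplied by the number of tests (capped at 1).
#'
#' @param metrics data.frame or matrix, subjects x models
#' @return list with matrices `r`, `p` (adjusted) and `n_tests`
#' @export
cross_model_correlation <- function(metrics) {
  m <- as.matrix(metrics)
  assert_that(nrow(m) >= 3, "need at least 3 subjects")
  if (any(apply(m, 2, stats::sd) == 0))
    stop_degenerate("constant metric column: correlation undefined")
  k <- ncol(m)
  n_tests <- k * (k - 1) / 2
  r <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    ct <- stats::cor.test(m[, i], m[, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- min(1, n_tests * ct$p.value)
  }
  list(r = r, p = p, n_tests = n_tests)
}

#' Group report table
#'
#' Collects per-subject summaries into the released-data column layout.
#'
#' @param summaries list of subject summaries from [run_subject()]
#' @return data.frame with columns subject, excluded, SPOC_LAMBDA,
#'   SPOC_CORR, SPOC_Pvalue, CSP_acc, CSP_Pvalues, CSP_auc,
#'   CSP_auc_Pvalues, LSTM_acc, LSTM_Pvalues
#' @export
group_report <- function(summaries) {
  g <- function(field) vapply(summaries, function(s)
    as.numeric(s[[field]] %||% NA_real_), numeric(1))
  data.frame(subject = vapply(summaries, function(s) s$subject, character(1)),
             excluded = vapply(summaries, function(s) isTRUE(s$excluded),
                               logical(1)),
             SPOC_LAMBDA = g("spoc_lambda"), SPOC_CORR = g("spoc_r"),
             SPOC_Pvalue = g("spoc_p"), CSP_acc = g("csp_acc"),
             CSP_Pvalues = g("csp_p"), CSP_auc = g("csp_auc"),
             CSP_auc_Pvalues = g("csp_auc_p"), LSTM_acc = g("lstm_acc"),
             LSTM_Pvalues = g("lstm_p"))
}
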