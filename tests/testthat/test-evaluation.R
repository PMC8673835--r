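# Subject- and group-level statistics and the break-exclusion control.

test_that("exact binomial test matches brute-force pmf summation", {
  # oracle: sum all outcome probabilities not exceeding the observed one
  brute_two_sided <- function(k, n, p0 = 0.5) {
    d <- dbinom(0:n, n, p0)
    sum(d[d <= d[k + 1] * (1 + 1e-7)])
  }
  for (n in c(1:20, 60, 121, 180, 199, 200)) {
    for (k in unique(round(seq(0, n, length.out = 9)))) {
      expect_equal(exact_binomial_test(k, n),
                   min(1, brute_two_sided(k, n)), tolerance = 1e-12)
    }
  }
  expect_equal(exact_binomial_test(90, 180), 1, tolerance = 0.01)
  expect_equal(exact_binomial_test(180, 180), 2 * 0.5^180)
  # smallest significant count at n = 180, one-sided (cumulative oracle)
  k_star <- 0
  for (k in 0:180) {
    if (sum(dbinom(k:180, 180, 0.5)) < 0.05) { k_star <- k; break }
  }
  expect_lt(exact_binomial_test(k_star, 180, sided = "greater"), 0.05)
  expect_gte(exact_binomial_test(k_star - 1, 180, sided = "greater"), 0.05)
  expect_error(exact_binomial_test(200, 180), "n_total")
})

test_that("group mean test is an upper-tail one-sample t", {
  flat <- group_mean_test(c(0.5, 0.5, 0.5, 0.5) + c(-1, 1, -1, 1) * 1e-9)
  expect_equal(flat$t, 0, tolerance = 1e-3)
  expect_equal(flat$p, 0.5, tolerance = 1e-3)
  expect_error(group_mean_test(rep(0.6, 26)), "variance")
  expect_error(group_mean_test(c(0.6, 0.7)), "at least 3")
  # hand-computed five-value example
  x <- c(0.55, 0.62, 0.48, 0.66, 0.58)
  t_hand <- (mean(x) - 0.5) / (sd(x) / sqrt(5))
  out <- group_mean_test(x)
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$p, 1 - pt(t_hand, 4), tolerance = 1e-12)
})

test_that("the 2x2 repeated-measures ANOVA decomposes within-subject effects", {
  acc <- array(0.6, dim = c(8, 2, 2),
               dimnames = list(NULL, c("csp", "lstm"), c("a", "b")))
  out0 <- rm_anova_2x2(acc)
  expect_equal(out0$F, c(0, 0, 0))
  expect_equal(out0$p, c(1, 1, 1))
  set.seed(1)
  base <- array(0.6 + rnorm(32, sd = 0.03), dim = c(8, 2, 2),
                dimnames = dimnames(acc))
  shifted <- base
  shifted[, "lstm", ] <- shifted[, "lstm", ] + 0.05
  out <- rm_anova_2x2(shifted)
  expect_gt(out["model", "F"], rm_anova_2x2(base)["model", "F"])
  expect_equal(out["model", "df1"], 1)
  expect_equal(out["model", "df2"], 7)
  # adding a constant to one model shifts only the model main effect
  expect_lt(out["interaction", "F"] / out["model", "F"], 0.5)
  # permutation of subject rows leaves all F unchanged
  perm <- shifted[sample(8), , ]
  dimnames(perm) <- dimnames(shifted)
  expect_equal(rm_anova_2x2(perm)$F, out$F, tolerance = 1e-9)
  expect_error(rm_anova_2x2(array(1, dim = c(1, 2, 2))), "2 complete")
})

test_that("paired comparison follows the textbook paired t", {
  same <- paired_comparison(c(0.6, 0.7, 0.65), c(0.6, 0.7, 0.65))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(paired_comparison(c(0.6, 0.7, 0.65) + 0.1,
                                 c(0.6, 0.7, 0.65)), "zero-variance")
  a <- c(0.61, 0.58, 0.70, 0.66)
  b <- c(0.55, 0.59, 0.64, 0.60)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  out <- paired_comparison(a, b)
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$p, 2 * (1 - pt(abs(t_hand), 3)), tolerance = 1e-12)
  expect_error(paired_comparison(1:4, 1:3), "equal length")
})

test_that("cross-model correlations apply the Bonferroni rule", {
  set.seed(2)
  x <- rnorm(12)
  m <- cbind(csp = x + rnorm(12, sd = 0.2),
             lstm = x + rnorm(12, sd = 0.2),
             spoc = rnorm(12))
  out <- cross_model_correlation(m)
  expect_equal(unname(diag(out$r)), rep(1, 3))
  expect_gt(out$r["csp", "lstm"], 0)
  expect_equal(out$n_tests, 3)
  raw_p <- cor.test(m[, "csp"], m[, "spoc"])$p.value
  expect_equal(out$p["csp", "spoc"], min(1, 3 * raw_p))
  expect_true(all(out$p[upper.tri(out$p)] <= 1))
  expect_error(cross_model_correlation(cbind(rep(1, 5), rnorm(5))),
               "constant")
})

test_that("decoders trained on a shared planted signal correlate", {
  # subjects with graded coupling strength: both decoders should track it
  kappas <- seq(0.15, 0.8, length.out = 8)
  metrics <- t(sapply(seq_along(kappas), function(i) {
    d <- subject_decoding_inputs(synth_config(seed = 300 + i,
                                              coupling_kappa = kappas[i]))
    bl <- arousalpha:::binary_labels(d$labels)
    cov <- arousalpha:::subset_cov(d$cov, bl$idx)
    c(acc = randomized_cv(cov, bl$y, seed = 1)$mean_accuracy,
      auc = subblocked_cv(cov, bl$y, seed = 1)$roc_auc)
  }))
  out <- cross_model_correlation(metrics)
  expect_gt(out$r[1, 2], 0)
})

test_that("the break-exclusion control reruns the chain on 240 s", {
  cfg <- run_config(synth = synth_config(seed = 21), n_perm = 100)
  ctrl <- run_break_exclusion_control(cfg)
  wo <- ctrl$without_break
  expect_length(wo$trace$values, 240)
  expect_equal(as.integer(table(wo$artifacts$labels$classes)),
               c(80, 80, 80))
  expect_equal(nrow(ctrl$paired), 2)
  expect_true(all(is.finite(ctrl$paired$with_break)))
  expect_true(all(is.finite(ctrl$paired$without_break)))
  # planted coupling survives removal of the low-arousal break
  expect_gte(wo$summary$csp_auc, 0.65)
})

test_that("group reports collect the released-data columns", {
  cfg <- run_config(synth = synth_config(seed = 21), n_perm = 100)
  res <- run_subject(cfg)
  rep <- group_report(list(res$summary))
  expect_true(all(c("SPOC_LAMBDA", "SPOC_CORR", "SPOC_Pvalue", "CSP_acc",
                    "CSP_Pvalues", "LSTM_acc", "LSTM_Pvalues") %in%
                    names(rep)))
  expect_false(rep$excluded[1])
  expect_true(is.na(rep$LSTM_acc[1]))
})
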