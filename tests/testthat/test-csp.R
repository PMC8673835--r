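# CSP decomposition, features, shrinkage LDA, CV schemes, SMOTE,
# block-permutation nulls.

# covariance stack with prescribed class covariance matrices
two_class_cov <- function(C_lo, C_hi, n_per = 10) {
  k <- nrow(C_lo)
  C <- array(0, dim = c(k, k, 2 * n_per))
  for (e in seq_len(n_per)) C[, , e] <- C_lo
  for (e in seq_len(n_per)) C[, , n_per + e] <- C_hi
  list(cov = structure(list(C = C,
                            Cbar = (C_lo + C_hi) / 2,
                            n_epochs = 2 * n_per),
                       class = "epoch_covariances"),
       y = factor(rep(c("low", "high"), each = n_per),
                  levels = c("low", "high")))
}

test_that("identical class covariances give eigenvalues of one half", {
  set.seed(1)
  A <- crossprod(matrix(rnorm(25), 5))
  tc <- two_class_cov(A, A)
  res <- csp_decompose(tc$cov, tc$y)
  expect_equal(res$eigenvalues, rep(0.5, 5), tolerance = 1e-8)
})

test_that("a 4:1 planted variance ratio yields the analytic eigenvalue", {
  tc <- two_class_cov(diag(c(1, 1)), diag(c(4, 1)))
  res <- csp_decompose(tc$cov, tc$y)
  expect_equal(res$eigenvalues[1], 4 / 5, tolerance = 1e-10)
  expect_equal(res$eigenvalues[2], 1 / 2, tolerance = 1e-10)
})

test_that("label swap maps eigenvalues to their complement in reverse", {
  set.seed(2)
  C1 <- crossprod(matrix(rnorm(36), 6)) / 6
  C2 <- crossprod(matrix(rnorm(36), 6)) / 6
  tc <- two_class_cov(C1, C2)
  res <- csp_decompose(tc$cov, tc$y)
  swapped <- csp_decompose(tc$cov,
                           factor(ifelse(tc$y == "low", "high", "low"),
                                  levels = c("low", "high")))
  expect_equal(swapped$eigenvalues, rev(1 - res$eigenvalues),
               tolerance = 1e-8)
  expect_error(csp_decompose(tc$cov, factor(rep("high", 20),
                                            levels = c("low", "high"))),
               "2 epochs per class")
})

test_that("log-variance features obey scaling identities", {
  d <- planted_subject()
  bl <- arousalpha:::binary_labels(d$labels)
  cov <- arousalpha:::subset_cov(d$cov, bl$idx)
  res <- csp_decompose(cov, bl$y)
  fe <- csp_features(cov, res)
  expect_equal(dim(fe), c(cov$n_epochs, 4))
  # scaling an epoch's data by c scales its covariance by c^2:
  cov2 <- cov
  cov2$C[, , 3] <- 4 * cov2$C[, , 3]
  fe2 <- csp_features(cov2, res)
  expect_equal(fe2[3, ], fe[3, ] + 2 * log(2), tolerance = 1e-10)
  expect_equal(fe2[-3, ], fe[-3, ], tolerance = 1e-12)
  # unit-variance epochs through an identity filter give zero features
  k <- nrow(cov$Cbar)
  unit <- structure(list(C = array(diag(k), c(k, k, 2)), Cbar = diag(k),
                         n_epochs = 2), class = "epoch_covariances")
  expect_equal(csp_features(unit, diag(k)),
               matrix(0, 2, k), tolerance = 1e-12)
})

test_that("shrinkage LDA separates separable data and stays bounded", {
  set.seed(4)
  f_tr <- matrix(c(rnorm(30, -1, 0.01), rnorm(30, 1, 0.01)), ncol = 1)
  y_tr <- factor(rep(c("low", "high"), each = 30), levels = c("low", "high"))
  clf <- lda_shrinkage(f_tr, y_tr)
  expect_equal(mean(predict(clf, f_tr)$class == y_tr), 1)
  expect_gte(clf$intensity, 0)
  expect_lte(clf$intensity, 1)
  # identical class means: held-out accuracy hovers at chance
  accs <- sapply(1:50, function(s) {
    set.seed(s)
    f <- matrix(rnorm(80 * 3), 80, 3)
    y <- factor(rep(c("low", "high"), 40), levels = c("low", "high"))
    cl <- lda_shrinkage(f[1:60, ], y[1:60])
    mean(predict(cl, f[61:80, ])$class == y[61:80])
  })
  expect_lt(abs(mean(accs) - 0.5), 0.06)
})

test_that("stratified folds partition the epochs evenly by class", {
  y <- factor(rep(c("low", "high"), each = 90), levels = c("low", "high"))
  folds <- make_cv_folds(y, k = 10, seed = 3)
  expect_length(folds, 10)
  expect_equal(sort(unlist(folds)), 1:180)
  for (f in folds) expect_equal(as.integer(table(y[f])), c(9, 9))
})

test_that("randomized CV decodes planted coupling and not shuffled labels", {
  d <- planted_subject()
  bl <- arousalpha:::binary_labels(d$labels)
  cov <- arousalpha:::subset_cov(d$cov, bl$idx)
  res <- randomized_cv(cov, bl$y, seed = 5)
  expect_gte(res$mean_accuracy, 0.7)
  expect_length(res$per_fold_accuracy, 10)
  expect_equal(mean(res$predictions == res$truth),
               mean(sapply(seq_along(res$folds), function(f)
                 mean(res$predictions[res$folds[[f]]] ==
                        res$truth[res$folds[[f]]]))),
               tolerance = 0.02)
  set.seed(9)
  y_shuf <- sample(bl$y)
  res0 <- randomized_cv(cov, y_shuf, seed = 5)
  expect_lt(abs(res0$mean_accuracy - 0.5), 0.1)
  expect_error(randomized_cv(cov, bl$y, k = 200), "k must")
})

test_that("training-fold filters ignore test-epoch perturbations", {
  d <- planted_subject()
  bl <- arousalpha:::binary_labels(d$labels)
  cov <- arousalpha:::subset_cov(d$cov, bl$idx)
  folds <- make_cv_folds(bl$y, k = 10, seed = 5)
  te <- folds[[1]]
  tr <- setdiff(seq_along(bl$y), te)
  w1 <- csp_decompose(arousalpha:::subset_cov(cov, tr), bl$y[tr])$filters_W
  cov_pert <- cov
  cov_pert$C[, , te[1]] <- 100 * cov_pert$C[, , te[1]]
  w2 <- csp_decompose(arousalpha:::subset_cov(cov_pert, tr),
                      bl$y[tr])$filters_W
  expect_identical(w1, w2)
})

test_that("SMOTE balances classes with convex minority combinations", {
  set.seed(6)
  f <- matrix(rnorm(30 * 2), 30, 2)
  y <- factor(c(rep("low", 10), rep("high", 20)), levels = c("low", "high"))
  out <- smote_oversample(f, y, seed = 2)
  expect_equal(as.integer(table(out$y)), c(20, 20))
  synth <- out$features[31:40, ]
  minn <- f[1:10, ]
  for (i in 1:10) {
    # componentwise betweenness: each synthetic point lies on a segment
    # between two original minority points
    inside <- apply(minn, 1, function(a) apply(minn, 1, function(b)
      all(synth[i, ] >= pmin(a, b) - 1e-12 &
            synth[i, ] <= pmax(a, b) + 1e-12)))
    expect_true(any(inside))
  }
  bal <- smote_oversample(f[1:20, ], factor(rep(c("low", "high"), 10)),
                          seed = 2)
  expect_equal(dim(bal$features), c(20, 2))
  expect_message(
    one <- smote_oversample(f, factor(c("low", rep("high", 29)),
                                      levels = c("low", "high")), seed = 2),
    "duplication")
  expect_equal(as.integer(table(one$y)), c(29, 29))
})

test_that("sub-blocked folds have the stated chunk structure", {
  folds <- arousalpha:::subblocked_folds(180, 3, 10)
  expect_length(folds, 10)
  expect_true(all(lengths(folds) == 18))
  expect_equal(sort(unlist(folds)), 1:180)
  expect_equal(folds[[1]], c(1:6, 61:66, 121:126))
  # remainder epochs land in the final chunk of each sub-block
  f2 <- arousalpha:::subblocked_folds(185, 3, 10)
  expect_equal(sort(unlist(f2)), 1:185)
  expect_gt(length(f2[[10]]), length(f2[[1]]))
})

test_that("sub-blocked CV reports fold AUCs on unbalanced test sets", {
  d <- planted_subject()
  bl <- arousalpha:::binary_labels(d$labels)
  cov <- arousalpha:::subset_cov(d$cov, bl$idx)
  res <- subblocked_cv(cov, bl$y, seed = 7)
  expect_gte(res$roc_auc, 0.65)
  expect_length(res$per_fold_auc, 10)
  expect_error(subblocked_cv(arousalpha:::subset_cov(cov, 1:20), bl$y[1:20],
                             n_subblocks = 3, k = 10), "fewer epochs")
})

test_that("internal rank AUC matches pROC on continuous scores", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- rep(c(TRUE, FALSE), 30)
  s <- rnorm(60) + y
  ours <- arousalpha:::auc_rank(y, s)
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("block permutation shuffles intact label blocks", {
  d <- planted_subject()
  bl <- arousalpha:::binary_labels(d$labels)
  cov <- arousalpha:::subset_cov(d$cov, bl$idx)
  seen <- list()
  metric <- function(cc, yy) { seen[[length(seen) + 1]] <<- yy; 0.5 }
  out <- block_permutation_test(cov, bl$y, metric, n_blocks = 10,
                                n_perm = 20, seed = 3)
  expect_equal(out$observed, 0.5)
  blocks <- split(as.character(bl$y), rep(1:10, each = 18))
  key <- unname(vapply(blocks, paste, collapse = "", character(1)))
  for (yy in seen[-1]) {            # first call is the observed metric
    perm_key <- unname(vapply(split(as.character(yy), rep(1:10, each = 18)),
                              paste, collapse = "", character(1)))
    expect_setequal(perm_key, key)  # every block appears intact
  }
  # identity permutation reproduces the observed metric exactly
  m2 <- function(cc, yy) mean(yy == "high") + sum(which(yy == "high"))
  out2 <- block_permutation_test(cov, bl$y, m2, n_perm = 50, seed = 4)
  ident <- m2(cov, bl$y)
  expect_equal(out2$observed, ident)
})

test_that("compiled block permutation matches the R metric on balanced folds", {
  d <- planted_subject()
  bl <- arousalpha:::binary_labels(d$labels)
  cov <- arousalpha:::subset_cov(d$cov, bl$idx)
  y_alt <- factor(rep(c("low", "high"), 90), levels = c("low", "high"))
  r_metric <- subblocked_auc(cov, y_alt, seed = 3)
  cpp <- csp_block_permutation(cov, y_alt, n_perm = 100, seed = 3)
  expect_equal(cpp$observed, r_metric, tolerance = 1e-12)
  expect_length(cpp$null, 100)
  expect_gte(cpp$p_value, 1 / 101)
  expect_lte(cpp$p_value, 1)
})

test_that("prediction rows mirror the released table coding", {
  d <- planted_subject()
  bl <- arousalpha:::binary_labels(d$labels)
  cov <- arousalpha:::subset_cov(d$cov, bl$idx)
  res <- randomized_cv(cov, bl$y, seed = 5)
  row <- prediction_row(res, d$labels)
  expect_length(row, 270)
  expect_equal(sum(is.na(row)), 90)                  # mid tertile
  expect_true(all(row[!is.na(row)] %in% c(0, 1)))
})
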