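# Binary decoding of high vs low arousal: CSP decomposition, log-variance
# features, analytic-shrinkage LDA, randomized and sub-blocked
# cross-validation, SMOTE balancing, and block-permutation nulls.

as_epoch_cov <- function(x) {
  if (inherits(x, "epoch_covariances")) x else epoch_covariances(x)
}

# Normalize labels to a low/high factor over retained (non-mid) epochs.
# Accepts a label_set (mid discarded) or a two-level factor/character.
binary_labels <- function(labels) {
  if (inherits(labels, "label_set")) {
    idx <- which(labels$classes != "mid")
    y <- factor(as.character(labels$classes[idx]), levels = c("low", "high"))
  } else {
    y <- factor(as.character(labels), levels = c("low", "high"))
    assert_that(!anyNA(y), "labels must be 'low'/'high'")
    idx <- seq_along(y)
  }
  list(idx = idx, y = y)
}

#' Common spatial patterns decomposition
#'
#' Generalized eigenproblem of (C_high, C_high + C_low) on class-mean
#' covariances (mean of per-epoch covariances per class). Eigenvalues lie
#' in (0, 1) and are sorted descending: the top filters maximize the
#' high-arousal variance share, the bottom ones the low-arousal share.
#'
#' @param x an `epoched_data` or precomputed [epoch_covariances()]
#' @param y factor with levels low/high, one per epoch of `x`
#' @param rank_tol rank-truncation tolerance for whitening
#' @param compute_patterns also invert the filter matrix? (skipped inside
#'   permutation loops where only filters are needed)
#' @return object of class `csp_result`: `filters_W`, `patterns_A`,
#'   `eigenvalues`, `feature_components` (two from each end)
#' @export
csp_decompose <- function(x, y, rank_tol = 1e-10, compute_patterns = TRUE) {
  cov <- as_epoch_cov(x)
  y <- factor(as.character(y), levels = c("low", "high"))
  assert_that(length(y) == cov$n_epochs, "one label per epoch required")
  if (any(table(y) < 2)) stop_invalid("need at least 2 epochs per class")
  k <- nrow(cov$Cbar)
  Cflat <- matrix(cov$C, nrow = k * k)
  C_hi <- matrix(rowMeans(Cflat[, y == "high", drop = FALSE]), k, k)
  C_lo <- matrix(rowMeans(Cflat[, y == "low", drop = FALSE]), k, k)
  P <- whitener(C_hi + C_lo, rank_tol)
  M <- t(P) %*% C_hi %*% P
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  W <- P %*% e$vectors
  A <- if (compute_patterns) t(MASS::ginv(W)) else NULL
  m <- ncol(W)
  structure(list(filters_W = W, patterns_A = A, eigenvalues = e$values,
                 feature_components = c(1L, 2L, m - 1L, m)),
            class = "csp_result")
}

#' Log-variance CSP features
#'
#' One feature per selected component: the logarithm of the variance of the
#' filtered epoch, `log(w' C(e) w)`, floored at a small epsilon.
#'
#' @param x an `epoched_data` or [epoch_covariances()]
#' @param csp a `csp_result` (or a filter matrix)
#' @param components component indices (default: two from each end)
#' @return epochs x components feature matrix
#' @export
csp_features <- function(x, csp, components = NULL) {
  cov <- as_epoch_cov(x)
  W <- if (inherits(csp, "csp_result")) csp$filters_W else as.matrix(csp)
  if (is.null(components))
    components <- if (inherits(csp, "csp_result")) csp$feature_components
                  else seq_len(ncol(W))
  k <- nrow(W)
  Wsq <- vapply(components, function(j)
    as.numeric(tcrossprod(W[, j])), numeric(k * k))
  feats <- crossprod(matrix(cov$C, nrow = k * k), Wsq)
  if (any(feats <= 0)) {
    message("flooring ", sum(feats <= 0), " non-positive projected variances")
    feats[feats <= 0] <- 1e-12
  }
  log(feats)
}

# Ledoit-Wolf analytic shrinkage of a covariance estimate toward the
# scaled identity; returns the shrunk matrix and the intensity in [0, 1].
shrink_covariance <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / n
  m <- mean(diag(S))
  d2 <- sum((S - diag(m, p))^2)
  # (1/n^2) sum_i ||x_i x_i' - S||_F^2, expanded to vectorized form
  q <- rowSums(Xc^2)
  xSx <- rowSums((Xc %*% S) * Xc)
  b2bar <- (sum(q^2) - 2 * sum(xSx) + n * sum(S^2)) / n^2
  b2 <- min(b2bar, d2)
  rho <- if (d2 > 0) b2 / d2 else 1
  list(sigma = rho * diag(m, p) + (1 - rho) * S, intensity = rho)
}

#' Linear discriminant analysis with analytic covariance shrinkage
#'
#' Two-class LDA whose pooled covariance is regularized by the analytic
#' (Ledoit-Wolf) shrinkage solution. Decision scores are signed distances
#' to the class boundary (positive = high arousal).
#'
#' @param features training feature matrix (epochs x features)
#' @param y factor with levels low/high
#' @return object of class `lda_shrinkage` with weights, bias and the
#'   shrinkage `intensity`
#' @export
lda_shrinkage <- function(features, y) {
  features <- as.matrix(features)
  y <- factor(as.character(y), levels = c("low", "high"))
  assert_that(all(table(y) > 0), "both classes required in training set")
  mu0 <- colMeans(features[y == "low", , drop = FALSE])
  mu1 <- colMeans(features[y == "high", , drop = FALSE])
  Xc <- rbind(sweep(features[y == "low", , drop = FALSE], 2, mu0),
              sweep(features[y == "high", , drop = FALSE], 2, mu1))
  sh <- shrink_covariance(Xc)
  w <- solve(sh$sigma, mu1 - mu0)
  b <- -sum(w * (mu1 + mu0)) / 2
  structure(list(w = w, b = b, intensity = sh$intensity),
            class = "lda_shrinkage")
}

#' @param object an `lda_shrinkage` classifier
#' @param newdata feature matrix to classify
#' @param ... unused
#' @return list with `class` (factor low/high) and numeric `score`
#' @rdname lda_shrinkage
#' @export
predict.lda_shrinkage <- function(object, newdata, ...) {
  s <- as.numeric(as.matrix(newdata) %*% object$w + object$b)
  list(class = factor(ifelse(s > 0, "high", "low"), levels = c("low", "high")),
       score = s)
}

#' Cross-validation folds
#'
#' Randomized (optionally class-stratified) k-fold assignment; returned as
#' a list of test index vectors. Shared between the CSP and LSTM decoders
#' so their accuracies are comparable.
#'
#' @param y label factor (used for stratification)
#' @param k number of folds
#' @param seed integer seed
#' @param stratified stratify fold assignment by class?
#' @return list of `k` integer vectors of test indices
#' @export
make_cv_folds <- function(y, k = 10, seed = 1L, stratified = TRUE) {
  n <- length(y)
  assert_that(k >= 2 && k <= n, "k must lie in [2, n]")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(n)
  if (stratified) {
    for (cl in levels(factor(y))) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  lapply(seq_len(k), function(f) which(fold == f))
}

#' Randomized 10-fold CSP cross-validation (accuracy branch)
#'
#' Per fold, CSP filters and the shrinkage-LDA classifier are fitted on the
#' training split only; test-split predictions across folds are pooled into
#' one prediction per retained epoch. Accuracy is 1 minus the
#' misclassification rate, averaged over folds.
#'
#' @param x an `epoched_data` or [epoch_covariances()] of the retained
#'   (non-mid) epochs, or of all epochs when `labels` is a `label_set`
#' @param labels a `label_set` (mid discarded internally) or low/high factor
#' @param k number of folds
#' @param seed integer seed
#' @param folds optional precomputed fold list (overrides `k`/`seed`)
#' @return object of class `csp_cv_result`: `per_fold_accuracy`,
#'   `mean_accuracy`, pooled `predictions`/`scores`/`truth`, `folds`, and a
#'   full-data `csp` decomposition for pattern inspection
#' @export
randomized_cv <- function(x, labels, k = 10, seed = 1L, folds = NULL) {
  cov <- as_epoch_cov(x)
  bl <- binary_labels(labels)
  if (length(bl$idx) != cov$n_epochs)
    cov <- subset_cov(cov, bl$idx)
  y <- bl$y
  if (is.null(folds)) folds <- make_cv_folds(y, k, seed)
  pred <- factor(rep(NA, length(y)), levels = c("low", "high"))
  score <- numeric(length(y))
  acc <- numeric(length(folds))
  for (f in seq_along(folds)) {
    te <- folds[[f]]; tr <- setdiff(seq_along(y), te)
    csp <- csp_decompose(subset_cov(cov, tr), y[tr], compute_patterns = FALSE)
    fe_tr <- csp_features(subset_cov(cov, tr), csp)
    fe_te <- csp_features(subset_cov(cov, te), csp)
    clf <- lda_shrinkage(fe_tr, y[tr])
    p <- predict(clf, fe_te)
    pred[te] <- p$class; score[te] <- p$score
    acc[f] <- mean(p$class == y[te])
  }
  structure(list(per_fold_accuracy = acc, mean_accuracy = mean(acc),
                 predictions = pred, scores = score, truth = y,
                 folds = folds, csp = csp_decompose(cov, y)),
            class = "csp_cv_result")
}

subset_cov <- function(cov, idx) {
  k <- nrow(cov$Cbar)
  Csub <- cov$C[, , idx, drop = FALSE]
  structure(list(C = Csub,
                 Cbar = matrix(rowMeans(matrix(Csub, k * k)), k, k),
                 n_epochs = length(idx)),
            class = "epoch_covariances")
}

#' SMOTE oversampling of the minority class
#'
#' Synthetic minority points are convex combinations of a minority sample
#' and one of its `k_neighbors` minority nearest neighbours (Euclidean);
#' with a single minority sample the fallback is duplication.
#'
#' @param features feature matrix
#' @param y label factor
#' @param k_neighbors number of minority nearest neighbours
#' @param seed integer seed
#' @return list with balanced `features` and `y`
#' @export
smote_oversample <- function(features, y, k_neighbors = 5, seed = 1L) {
  features <- as.matrix(features)
  y <- factor(y)
  tab <- table(y)
  if (length(unique(tab)) == 1) return(list(features = features, y = y))
  minority <- names(tab)[which.min(tab)]
  need <- max(tab) - min(tab)
  mi <- which(y == minority)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (length(mi) == 1) {
    message("single minority sample: falling back to duplication")
    synth <- features[rep(mi, need), , drop = FALSE]
  } else {
    Xm <- features[mi, , drop = FALSE]
    kn <- min(k_neighbors, length(mi) - 1)
    base <- sample(length(mi), need, replace = TRUE)
    # neighbour search only for the sampled base points
    pick <- vapply(base, function(i) {
      d <- colSums((t(Xm) - Xm[i, ])^2)
      d[i] <- Inf
      nn <- order(d)[seq_len(kn)]
      nn[sample.int(kn, 1)]
    }, integer(1))
    u <- runif(need)
    synth <- Xm[base, , drop = FALSE] +
      u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  }
  list(features = rbind(features, synth),
       y = factor(c(as.character(y), rep(minority, need)),
                  levels = levels(y)))
}

#' Sub-blocked chronological cross-validation (ROC-AUC branch)
#'
#' The retained epochs are split chronologically into `n_subblocks` equal
#' sub-blocks; fold f's test set concatenates the f-th consecutive chunk
#' (length N / (k * n_subblocks)) from each sub-block, so test sets sample
#' all parts of the experience while temporal neighbourhoods stay intact.
#' SMOTE balances the training features only; the test set is left
#' unbalanced, and performance is the ROC-AUC of the LDA decision scores
#' (high arousal = positive class), averaged over folds.
#'
#' @inheritParams randomized_cv
#' @param n_subblocks number of chronological sub-blocks
#' @return object of class `csp_cv_result` with `per_fold_auc` and
#'   `roc_auc` in place of pooled accuracy
#' @export
subblocked_cv <- function(x, labels, n_subblocks = 3, k = 10, seed = 1L) {
  cov <- as_epoch_cov(x)
  bl <- binary_labels(labels)
  if (length(bl$idx) != cov$n_epochs)
    cov <- subset_cov(cov, bl$idx)
  y <- bl$y
  run <- subblocked_run(cov, y, n_subblocks, k, seed)
  structure(list(per_fold_auc = run$auc,
                 roc_auc = mean(run$auc, na.rm = TRUE),
                 predictions = run$pred, scores = run$score, truth = y,
                 folds = run$folds, csp = csp_decompose(cov, y)),
            class = "csp_cv_result")
}

# Shared fold loop of the sub-blocked CV (also drives the
# block-permutation metric, where the pattern fit would be wasted work).
subblocked_run <- function(cov, y, n_subblocks, k, seed) {
  n <- length(y)
  if (n < k * n_subblocks) stop_invalid("fewer epochs than k * n_subblocks")
  folds <- subblocked_folds(n, n_subblocks, k)
  auc <- rep(NA_real_, k)
  pred <- factor(rep(NA, n), levels = c("low", "high"))
  score <- numeric(n)
  for (f in seq_len(k)) {
    te <- folds[[f]]; tr <- setdiff(seq_len(n), te)
    csp <- csp_decompose(subset_cov(cov, tr), y[tr], compute_patterns = FALSE)
    fe_tr <- csp_features(subset_cov(cov, tr), csp)
    fe_te <- csp_features(subset_cov(cov, te), csp)
    bal <- smote_oversample(fe_tr, y[tr], seed = derive_seed(seed, f))
    clf <- lda_shrinkage(bal$features, bal$y)
    p <- predict(clf, fe_te)
    pred[te] <- p$class; score[te] <- p$score
    if (length(unique(y[te])) == 2)
      auc[f] <- auc_rank(y[te] == "high", p$score)
  }
  list(auc = auc, pred = pred, score = score, folds = folds)
}

#' Sub-blocked cross-validated ROC-AUC (metric only)
#'
#' Fast path returning just the fold-mean AUC; intended as the `metric_fn`
#' of [block_permutation_test()].
#'
#' @inheritParams subblocked_cv
#' @param y low/high factor over the epochs of `x`
#' @return mean ROC-AUC over folds
#' @export
subblocked_auc <- function(x, y, n_subblocks = 3, k = 10, seed = 1L) {
  cov <- as_epoch_cov(x)
  y <- factor(as.character(y), levels = c("low", "high"))
  mean(subblocked_run(cov, y, n_subblocks, k, seed)$auc, na.rm = TRUE)
}

# Chronological sub-blocked fold index sets; remainder epochs are appended
# to the final chunk of each sub-block.
subblocked_folds <- function(n, n_subblocks, k) {
  sb_len <- n %/% n_subblocks
  starts <- (seq_len(n_subblocks) - 1) * sb_len
  chunk <- sb_len %/% k
  lapply(seq_len(k), function(f) {
    unlist(lapply(seq_len(n_subblocks), function(b) {
      lo <- starts[b] + (f - 1) * chunk + 1
      hi <- if (f == k) {
        if (b == n_subblocks) n else starts[b] + sb_len
      } else starts[b] + f * chunk
      seq(lo, hi)
    }))
  })
}

#' Block permutation test for a decoding metric
#'
#' The chronological label series is split into `n_blocks` equally sized
#' contiguous blocks which are shuffled as units (internal order intact),
#' preserving local autocorrelation; the metric is recomputed on each
#' permuted series and the p-value is the upper-tail percentile rank of the
#' observed metric with the +1 correction.
#'
#' @param x an `epoched_data` or [epoch_covariances()] of the retained
#'   epochs, in chronological order
#' @param y low/high factor in chronological order
#' @param metric_fn function(x, y) returning a scalar decoding metric
#' @param n_blocks number of permutation blocks
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return list with `observed`, `null` and `p_value`
#' @export
block_permutation_test <- function(x, y, metric_fn, n_blocks = 10,
                                   n_perm = 1000, seed = 1L) {
  cov <- as_epoch_cov(x)
  y <- factor(as.character(y), levels = c("low", "high"))
  n <- length(y)
  assert_that(n_blocks <= n, "more blocks than epochs")
  observed <- metric_fn(cov, y)
  blocks <- split(seq_len(n), rep(seq_len(n_blocks), each = ceiling(n / n_blocks),
                                  length.out = n))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    yp <- y[unlist(blocks[sample(n_blocks)])]
    metric_fn(cov, yp)
  }, numeric(1))
  list(observed = observed, null = null,
       p_value = perm_pvalue(sum(null >= observed), n_perm))
}

#' Prediction table row in the released-data format
#'
#' One row per second of the experience: 1 = predicted high, 0 = predicted
#' low, NA = mid-tertile (not decoded).
#'
#' @param cv a `csp_cv_result`
#' @param labels the full `label_set` over all epochs
#' @return integer vector, one entry per epoch
#' @export
prediction_row <- function(cv, labels) {
  out <- rep(NA_integer_, length(labels$classes))
  out[labels$classes != "mid"] <- as.integer(cv$predictions == "high")
  out
}

#' Block-permutation null for the sub-blocked CSP decoder
#'
#' Specialized fast engine for the standard evaluation: the sub-blocked
#' cross-validated ROC-AUC recomputed under block-shuffled labels, with the
#' entire permutation loop run in compiled code. Equivalent in structure to
#' [block_permutation_test()] with [subblocked_auc()] as the metric.
#'
#' @inheritParams block_permutation_test
#' @inheritParams subblocked_cv
#' @return list with `observed`, `null` and `p_value`
#' @export
csp_block_permutation <- function(x, y, n_subblocks = 3, k = 10,
                                  n_blocks = 10, n_perm = 1000, seed = 1L) {
  cov <- as_epoch_cov(x)
  y <- factor(as.character(y), levels = c("low", "high"))
  assert_that(length(y) == cov$n_epochs, "one label per epoch required")
  assert_that(n_blocks <= length(y), "more blocks than epochs")
  .csp_blockperm_cpp(cov$C, as.integer(y == "high"), n_subblocks, k,
                     n_blocks, n_perm, as.integer(seed))
}
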