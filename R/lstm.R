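# LSTM decoder: a small recurrent sequence classifier over 1-s epochs of
# SSD components, with the constrained architecture space and two-step
# random hyperparameter search.

hp_layer_grid <- c(10, 15, 20, 25, 30, 40, 50, 65, 80, 100)
hp_lambda_grid <- c(0.00, 0.18, 0.36, 0.72, 1.44)
hp_lr_grid <- c(1e-2, 1e-3, 5e-4)

#' LSTM hyperparameter configuration
#'
#' Validates a configuration against the constrained search space: at most
#' two LSTM layers followed by at most two fully connected hidden layers,
#' layer sizes from \{10, 15, 20, 25, 30, 40, 50, 65, 80, 100\} with each
#' successive layer equal or smaller (bottleneck), ReLU or ELU activations,
#' L1/L2 regularization with strength in \{0, 0.18, 0.36, 0.72, 1.44\},
#' learning rate in \{1e-2, 1e-3, 5e-4\}, 1-10 input components, mini-batch
#' size 9, 20 training passes.
#'
#' @param lstm_sizes sizes of the 1-2 LSTM layers
#' @param fc_sizes sizes of the 1-2 fully connected hidden layers
#' @param activation "relu" or "elu"
#' @param regularizer "none", "l1" or "l2"
#' @param reg_lambda regularization strength
#' @param learning_rate Adam learning rate
#' @param n_components number of SSD component slots fed to the model
#' @param batch_size mini-batch size
#' @param n_epochs_train training passes over the data
#' @param seed integer seed for weight init and batch shuffling
#' @return object of class `hp_config`
#' @export
hp_config <- function(lstm_sizes = 25, fc_sizes = 10, activation = "relu",
                      regularizer = "none", reg_lambda = 0,
                      learning_rate = 1e-3, n_components = 10,
                      batch_size = 9, n_epochs_train = 20, seed = 1L) {
  assert_that(length(lstm_sizes) %in% 1:2, "1 or 2 LSTM layers required")
  assert_that(length(fc_sizes) %in% 1:2, "1 or 2 FC hidden layers required")
  assert_that(all(c(lstm_sizes, fc_sizes) %in% hp_layer_grid),
              "layer sizes must come from the predefined grid")
  sizes <- c(lstm_sizes, fc_sizes)
  if (any(diff(sizes) > 0))
    stop_invalid("bottleneck violation: successive layers must not grow")
  activation <- match.arg(activation, c("relu", "elu"))
  regularizer <- match.arg(regularizer, c("none", "l1", "l2"))
  assert_that(regularizer == "none" || reg_lambda %in% hp_lambda_grid,
              "regularization strength must come from the predefined grid")
  assert_that(learning_rate %in% hp_lr_grid,
              "learning rate must come from the predefined grid")
  assert_that(n_components >= 1 && n_components <= 10,
              "n_components must lie in [1, 10]")
  structure(list(lstm_sizes = as.integer(lstm_sizes),
                 fc_sizes = as.integer(fc_sizes),
                 activation = activation, regularizer = regularizer,
                 reg_lambda = if (regularizer == "none") 0 else reg_lambda,
                 learning_rate = learning_rate,
                 n_components = as.integer(n_components),
                 batch_size = as.integer(batch_size),
                 n_epochs_train = as.integer(n_epochs_train),
                 seed = as.integer(seed)),
            class = "hp_config")
}

#' Build the LSTM input tensor
#'
#' Assembles the epochs x samples x 10 tensor (component slots beyond the
#' available ones are zero vectors), then drops the mid-tertile rows,
#' leaving labels in \{-1, +1\} (+1 = high arousal).
#'
#' @param epochs an `epoched_data` in SSD space (signal-band filtered)
#' @param labels a `label_set` over the same epochs
#' @param n_components number of leading components fed in (<= 10)
#' @return object of class `lstm_dataset`: `tensor`
#'   (retained epochs x samples x 10), `y` in \{-1, +1\}, `retained`
#'   (indices into the original epochs)
#' @export
build_lstm_dataset <- function(epochs, labels, n_components = 10) {
  stopifnot(inherits(epochs, "epoched_data"), inherits(labels, "label_set"))
  d <- dim(epochs$tensor)
  assert_that(n_components <= 10, "n_components must be <= 10")
  n_avail <- min(n_components, d[3])
  tens <- array(0, dim = c(d[1], d[2], 10L))
  tens[, , seq_len(n_avail)] <- epochs$tensor[, , seq_len(n_avail)]
  keep <- which(labels$classes != "mid")
  y <- ifelse(labels$classes[keep] == "high", 1, -1)
  structure(list(tensor = tens[keep, , , drop = FALSE], y = y,
                 retained = keep, fs = epochs$fs),
            class = "lstm_dataset")
}

# Per-slot scale factors from a training tensor: one SD per component slot
# (zero-padding slots keep scale 1). Global per-component scaling preserves
# the between-epoch variance differences the decoders rely on.
lstm_slot_scale <- function(tensor) {
  s <- apply(tensor, 3, stats::sd)
  s[s == 0] <- 1
  s
}

scale_tensor <- function(tensor, s) {
  for (ch in seq_along(s)) tensor[, , ch] <- tensor[, , ch] / s[ch]
  tensor
}

#' Train the LSTM classifier
#'
#' Forward pass: LSTM layer(s) over the epoch's samples, final hidden state
#' through the FC layer(s) with ReLU/ELU, scalar tanh output. MSE loss
#' against the -1/+1 labels, Adam updates on shuffled mini-batches of 9,
#' 20 passes over the training data. Reproducible given the config seed.
#'
#' @param dataset an `lstm_dataset` (training portion)
#' @param hp an [hp_config()]
#' @return object of class `lstm_model`: fitted weights, per-iteration
#'   training `loss`, final `weight_l2`, the slot `scale` used, and `hp`
#' @export
lstm_train <- function(dataset, hp = hp_config()) {
  stopifnot(inherits(dataset, "lstm_dataset"), inherits(hp, "hp_config"))
  assert_that(length(dataset$y) > 0, "empty training set")
  s <- lstm_slot_scale(dataset$tensor)
  X <- scale_tensor(dataset$tensor, s)
  reg <- match(hp$regularizer, c("none", "l1", "l2")) - 1L
  fit <- .lstm_train_cpp(X, dataset$y, hp$lstm_sizes, hp$fc_sizes,
                         match(hp$activation, c("relu", "elu")) - 1L,
                         reg, hp$reg_lambda, hp$learning_rate,
                         hp$n_epochs_train, hp$batch_size, hp$seed)
  structure(list(net = fit$net, loss = as.numeric(fit$iter_loss),
                 weight_l2 = fit$weight_l2, scale = s, hp = hp),
            class = "lstm_model")
}

#' @param object an `lstm_model`
#' @param newdata an `lstm_dataset` (or bare tensor) to classify
#' @param ... unused
#' @return list with `score` (tanh outputs in (-1, 1)) and `class`
#'   (+1/-1; an output of exactly 0 maps to +1 by convention)
#' @rdname lstm_train
#' @export
predict.lstm_model <- function(object, newdata, ...) {
  tens <- if (inherits(newdata, "lstm_dataset")) newdata$tensor else newdata
  tens <- scale_tensor(tens, object$scale)
  score <- as.numeric(.lstm_predict_cpp(object$net, tens))
  list(score = score, class = ifelse(score >= 0, 1, -1))
}

#' Cross-validated LSTM accuracy
#'
#' Uses the same randomized (stratified) 10-fold splits as the CSP decoder
#' so the two models are comparable; predictions over the test folds are
#' pooled into one prediction per retained epoch.
#'
#' @param dataset an `lstm_dataset`
#' @param hp an [hp_config()]
#' @param k number of folds
#' @param seed fold-assignment seed
#' @param folds optional precomputed fold list (e.g. the CSP folds)
#' @return list with `mean_accuracy`, `per_fold_accuracy`, pooled
#'   `predictions` and `scores`, and the `folds` used
#' @export
lstm_cv <- function(dataset, hp = hp_config(), k = 10, seed = 1L,
                    folds = NULL) {
  stopifnot(inherits(dataset, "lstm_dataset"))
  y <- dataset$y
  if (is.null(folds))
    folds <- make_cv_folds(factor(y), k, seed)
  pred <- numeric(length(y)); score <- numeric(length(y))
  acc <- numeric(length(folds))
  for (f in seq_along(folds)) {
    te <- folds[[f]]; tr <- setdiff(seq_along(y), te)
    train_ds <- structure(list(tensor = dataset$tensor[tr, , , drop = FALSE],
                               y = y[tr]), class = "lstm_dataset")
    model <- lstm_train(train_ds, hp)
    p <- predict(model, dataset$tensor[te, , , drop = FALSE])
    pred[te] <- p$class; score[te] <- p$score
    acc[f] <- mean(p$class == y[te])
  }
  list(mean_accuracy = mean(acc), per_fold_accuracy = acc,
       predictions = pred, scores = score, folds = folds)
}

#' Draw a random hyperparameter configuration
#'
#' Uniform draw from the constrained space; layer sizes are sorted
#' non-increasing to satisfy the bottleneck constraint.
#'
#' @param seed integer seed
#' @param n_components_max upper bound for the component-count draw
#' @return an [hp_config()]
#' @export
sample_hp <- function(seed = 1L, n_components_max = 10) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_lstm <- sample(1:2, 1); n_fc <- sample(1:2, 1)
  sizes <- sort(sample(hp_layer_grid, n_lstm + n_fc, replace = TRUE),
                decreasing = TRUE)
  reg <- sample(c("none", "l1", "l2"), 1)
  hp_config(lstm_sizes = sizes[seq_len(n_lstm)],
            fc_sizes = sizes[n_lstm + seq_len(n_fc)],
            activation = sample(c("relu", "elu"), 1),
            regularizer = reg,
            reg_lambda = if (reg == "none") 0 else sample(hp_lambda_grid, 1),
            learning_rate = sample(hp_lr_grid, 1),
            n_components = sample(n_components_max, 1),
            seed = derive_seed(seed, 99L))
}

#' Two-step random hyperparameter search
#'
#' Step 1: `n_draws` random configurations are evaluated (mean CV accuracy)
#' on a random subset of `n_subset` subjects; the two best per subset
#' subject are pooled. Step 2: the pooled candidates are evaluated on every
#' subject and the best per subject is returned. Ties break by draw order,
#' so the search is seed-deterministic.
#'
#' @param datasets named list of `lstm_dataset`s, one per subject
#' @param n_draws number of random configurations in step 1
#' @param n_subset number of subjects used in step 1
#' @param k CV folds
#' @param seed integer seed
#' @return list with `best` (per-subject `hp_config`), `best_accuracy`
#'   (per-subject CV accuracy) and the pooled `candidates`
#' @export
lstm_random_search <- function(datasets, n_draws = 20,
                               n_subset = min(10, length(datasets)),
                               k = 10, seed = 1L) {
  assert_that(n_draws >= 1, "need at least one draw")
  assert_that(length(datasets) >= 1, "no datasets supplied")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  subset_idx <- sample(length(datasets), n_subset)
  draws <- lapply(seq_len(n_draws), function(i) sample_hp(derive_seed(seed, i)))
  step1 <- lapply(subset_idx, function(s) {
    accs <- vapply(draws, function(hp)
      lstm_cv(datasets[[s]], hp, k = k, seed = seed)$mean_accuracy,
      numeric(1))
    order(accs, decreasing = TRUE)[seq_len(min(2, n_draws))]
  })
  cand_idx <- unique(unlist(step1))
  candidates <- draws[cand_idx]
  best <- vector("list", length(datasets))
  best_acc <- numeric(length(datasets))
  for (s in seq_along(datasets)) {
    accs <- vapply(candidates, function(hp)
      lstm_cv(datasets[[s]], hp, k = k, seed = seed)$mean_accuracy,
      numeric(1))
    j <- which.max(accs)           # ties break by candidate (draw) order
    best[[s]] <- candidates[[j]]
    best_acc[s] <- accs[j]
  }
  names(best) <- names(datasets)
  list(best = best, best_accuracy = best_acc, candidates = candidates)
}
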