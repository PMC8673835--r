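# LSTM decoder: configuration space, dataset assembly, training behaviour.

# small synthetic sequence dataset: class +1 has higher-variance signal in
# the first component slots
toy_dataset <- function(n_epochs = 40, n_samples = 50, seed = 1,
                        signal = TRUE) {
  set.seed(seed)
  y <- rep(c(-1, 1), length.out = n_epochs)
  tens <- array(rnorm(n_epochs * n_samples * 10, sd = 0.5),
                dim = c(n_epochs, n_samples, 10))
  if (signal)
    for (e in which(y == 1))
      tens[e, , 1:3] <- tens[e, , 1:3] * 3
  structure(list(tensor = tens, y = y), class = "lstm_dataset")
}

test_that("the hyperparameter space enforces its grids and bottleneck", {
  hp <- hp_config(lstm_sizes = c(50, 25), fc_sizes = c(25, 10),
                  activation = "elu", regularizer = "l2", reg_lambda = 0.36,
                  learning_rate = 1e-2, n_components = 5)
  expect_s3_class(hp, "hp_config")
  expect_error(hp_config(lstm_sizes = c(25, 50)), "bottleneck")
  expect_error(hp_config(lstm_sizes = 25, fc_sizes = 40), "bottleneck")
  expect_error(hp_config(lstm_sizes = 23), "grid")
  expect_error(hp_config(regularizer = "l1", reg_lambda = 0.5), "grid")
  expect_error(hp_config(learning_rate = 2e-3), "grid")
  expect_error(hp_config(n_components = 11), "1, 10")
  expect_error(hp_config(lstm_sizes = c(25, 25, 25)), "LSTM layers")
})

test_that("sampled configurations always satisfy the constraints", {
  for (s in 1:20) {
    hp <- sample_hp(seed = s)
    sizes <- c(hp$lstm_sizes, hp$fc_sizes)
    expect_true(all(sizes %in% c(10, 15, 20, 25, 30, 40, 50, 65, 80, 100)))
    expect_true(all(diff(sizes) <= 0))
    expect_true(hp$learning_rate %in% c(1e-2, 1e-3, 5e-4))
  }
  expect_identical(sample_hp(seed = 3), sample_hp(seed = 3))
})

test_that("dataset assembly pads slots and drops the mid tertile", {
  d <- planted_subject()
  ds <- build_lstm_dataset(d$epochs, d$labels)
  expect_equal(dim(ds$tensor), c(180, 250, 10))
  expect_true(all(ds$y %in% c(-1, 1)))
  expect_equal(sum(ds$y == 1), 90)
  n_avail <- dim(d$epochs$tensor)[3]
  for (slot in seq(n_avail + 1, 10))
    expect_true(all(ds$tensor[, , slot] == 0))
  ds3 <- build_lstm_dataset(d$epochs, d$labels, n_components = 3)
  expect_true(all(ds3$tensor[, , 4:10] == 0))
  expect_error(build_lstm_dataset(d$epochs, d$labels, n_components = 11),
               "<= 10")
})

test_that("training reduces the loss and stays in the tanh range", {
  losses <- sapply(1:10, function(s) {
    m <- lstm_train(toy_dataset(seed = s),
                    hp_config(lstm_sizes = 10, fc_sizes = 10, seed = s))
    m$loss
  })
  # median learning curve decreases over the first five iterations
  expect_lt(median(losses[5, ]), median(losses[1, ]))
  m <- lstm_train(toy_dataset(seed = 1), hp_config(seed = 1))
  p <- predict(m, toy_dataset(seed = 2))
  expect_true(all(p$score > -1 & p$score < 1))
  expect_true(all(p$class == ifelse(p$score >= 0, 1, -1)))
})

test_that("L2 regularization shrinks the final weight norm", {
  ds <- toy_dataset(seed = 4)
  base <- hp_config(lstm_sizes = 10, fc_sizes = 10, seed = 11)
  reg <- hp_config(lstm_sizes = 10, fc_sizes = 10, regularizer = "l2",
                   reg_lambda = 1.44, seed = 11)
  m0 <- lstm_train(ds, base)
  m2 <- lstm_train(ds, reg)
  expect_lt(m2$weight_l2, m0$weight_l2)
})

test_that("constant input yields chance-level held-out accuracy", {
  accs <- sapply(1:10, function(s) {
    ds <- toy_dataset(n_epochs = 60, seed = s, signal = FALSE)
    ds$tensor[] <- 0
    tr <- 1:40; te <- 41:60
    train <- structure(list(tensor = ds$tensor[tr, , ], y = ds$y[tr]),
                       class = "lstm_dataset")
    m <- lstm_train(train, hp_config(lstm_sizes = 10, fc_sizes = 10,
                                     seed = s))
    mean(predict(m, ds$tensor[te, , ])$class == ds$y[te])
  })
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("separable sequences are decoded above chance", {
  ds <- toy_dataset(n_epochs = 60, seed = 6)
  cv <- lstm_cv(ds, hp_config(lstm_sizes = 10, fc_sizes = 10,
                              learning_rate = 1e-2, seed = 2),
                k = 5, seed = 3)
  expect_gte(cv$mean_accuracy, 0.75)
})

test_that("LSTM CV can reuse the CSP fold object", {
  ds <- toy_dataset(n_epochs = 30, seed = 7)
  folds <- make_cv_folds(factor(ds$y), k = 3, seed = 5)
  cv <- lstm_cv(ds, hp_config(lstm_sizes = 10, fc_sizes = 10, seed = 2),
                folds = folds)
  expect_identical(cv$folds, folds)
})

test_that("random search is deterministic and picks a top candidate", {
  ds <- toy_dataset(n_epochs = 30, seed = 8)
  datasets <- list(a = ds)
  out1 <- lstm_random_search(datasets, n_draws = 3, n_subset = 1, k = 3,
                             seed = 9)
  out2 <- lstm_random_search(datasets, n_draws = 3, n_subset = 1, k = 3,
                             seed = 9)
  expect_identical(out1$best, out2$best)
  expect_gte(out1$best_accuracy[1],
             median(sapply(seq_len(3), function(i)
               lstm_cv(ds, sample_hp(derive_seed(9, i)), k = 3,
                       seed = 9)$mean_accuracy)))
  single <- lstm_random_search(datasets, n_draws = 1, n_subset = 1, k = 3,
                               seed = 2)
  expect_length(single$candidates, 1)
  expect_error(lstm_random_search(datasets, n_draws = 0), "at least one")
})
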