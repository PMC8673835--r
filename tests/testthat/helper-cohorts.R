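# Shared, lazily-computed simulation artifacts. Cohort-level statistics are
# expensive, so they are computed once per test run and cached for every
# test that needs them.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache))
    assign(key, force(expr), envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}

# SSD-space decoding inputs for one simulated subject: epoch covariances of
# the selected, signal-band-filtered components plus the trace and labels.
subject_decoding_inputs <- function(config) {
  sub <- generate_subject(config)
  rec <- sub$recording
  peak <- detect_alpha_peak(rec)
  ssd <- ssd_decompose(rec, ssd_bands(peak$alpha_peak_hz))
  sel <- select_components(ssd, peak$alpha_peak_hz)
  if (length(sel) < 2) sel <- 1:2  # decoding needs >= 2 components
  epochs <- epoch_data(ssd$components_signal[sel, , drop = FALSE],
                       fs = rec$fs)
  list(sub = sub, ssd = ssd, selected = sel, epochs = epochs,
       cov = epoch_covariances(epochs), trace = sub$trace,
       labels = tertile_labels(sub$trace))
}

# One planted high-SNR subject reused by SSD/SPoC/CSP/LSTM unit tests.
planted_subject <- function() {
  cached("planted", subject_decoding_inputs(synth_config(seed = 7)))
}

# Null-model cohort (coupling 0): per-subject SPoC permutation p-value,
# randomized-CV accuracy and block-permutation p-value, 200 permutations.
null_cohort <- function(n = 100, n_perm = 200, base_seed = 1000L) {
  cached(sprintf("null_%d_%d", n, n_perm), {
    rows <- lapply(seq_len(n), function(i) {
      seed <- derive_seed(base_seed, i)
      d <- subject_decoding_inputs(synth_config(seed = seed,
                                                coupling_kappa = 0))
      sp <- spoc_permutation_test(d$cov, d$trace$z, n_perm = n_perm,
                                  seed = derive_seed(seed, 11L))
      bl <- arousalpha:::binary_labels(d$labels)
      cvr <- arousalpha:::subset_cov(d$cov, bl$idx)
      rcv <- randomized_cv(cvr, bl$y, seed = derive_seed(seed, 12L))
      bp <- csp_block_permutation(cvr, bl$y, n_perm = n_perm,
                                  seed = derive_seed(seed, 14L))
      data.frame(spoc_p = sp$p_value, spoc_r = sp$r,
                 csp_acc = rcv$mean_accuracy, csp_bp_p = bp$p_value)
    })
    do.call(rbind, rows)
  })
}

# Planted-coupling cohort (kappa = 0.8, high in-band SNR): recovery metrics
# per simulated subject.
recovery_cohort <- function(n = 20, base_seed = 2000L) {
  cached(sprintf("recovery_%d", n), {
    rows <- lapply(seq_len(n), function(i) {
      seed <- derive_seed(base_seed, i)
      d <- subject_decoding_inputs(synth_config(seed = seed,
                                                coupling_kappa = 0.8))
      sp <- spoc_decompose(d$cov, d$trace$z)
      est <- estimate_target(sp, d$cov)
      patt <- d$ssd$patterns_A[, d$selected, drop = FALSE] %*%
        sp$patterns_A[, sp$chosen_index]
      psim <- abs(pattern_similarity(patt,
                                     d$sub$ground_truth$alpha_pattern))
      bl <- arousalpha:::binary_labels(d$labels)
      cvr <- arousalpha:::subset_cov(d$cov, bl$idx)
      rcv <- randomized_cv(cvr, bl$y, seed = derive_seed(seed, 12L))
      scv <- subblocked_cv(cvr, bl$y, seed = derive_seed(seed, 13L))
      data.frame(pattern_sim = psim, r = est$r,
                 csp_acc = rcv$mean_accuracy, csp_auc = scv$roc_auc)
    })
    do.call(rbind, rows)
  })
}

# Random epoch-covariance stacks for oracle-equivalence checks.
random_cov_stack <- function(k, n, seed) {
  set.seed(seed)
  C <- array(0, dim = c(k, k, n))
  for (e in seq_len(n)) {
    X <- matrix(rnorm(5 * k * k), 5 * k, k)
    C[, , e] <- crossprod(X) / (5 * k)
  }
  structure(list(C = C, Cbar = matrix(rowMeans(matrix(C, k * k)), k, k),
                 n_epochs = n),
            class = "epoch_covariances")
}

# Recording filled with the given channels x samples matrix.
recording_from_matrix <- function(X, fs = 250, marks = NULL) {
  if (is.null(marks)) marks <- c(0, ncol(X))
  arousalpha:::new_recording(X, fs, arousalpha:::eeg_channel_labels(nrow(X)),
                             marks, cropped = TRUE)
}
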