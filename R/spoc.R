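# Source power comodulation (SPoC_lambda): supervised decomposition tying
# per-epoch alpha-band variance to a continuous arousal target, with
# phase-randomized surrogate permutation testing.

#' Per-epoch covariance matrices
#'
#' Epoch-wise channel covariance of (typically SSD-space, signal-band
#' filtered) data, plus their mean; the per-epoch variance of a filtered
#' component `w' C(e) w` is the power proxy used throughout.
#'
#' @param epochs an `epoched_data` (epochs x samples x channels)
#' @return object of class `epoch_covariances`: `C` (k x k x N array),
#'   `Cbar` (mean covariance), `n_epochs`
#' @export
epoch_covariances <- function(epochs) {
  stopifnot(inherits(epochs, "epoched_data"))
  d <- dim(epochs$tensor)
  C <- array(0, dim = c(d[3], d[3], d[1]))
  for (e in seq_len(d[1]))
    C[, , e] <- stats::cov(epochs$tensor[e, , ])
  structure(list(C = C, Cbar = apply(C, c(1, 2), mean), n_epochs = d[1]),
            class = "epoch_covariances")
}

# Per-epoch variance series of filter w: v(e) = w' C(e) w, vectorized as a
# single matrix product over the flattened covariance stack.
filter_variance_series <- function(cov, w) {
  k <- nrow(cov$Cbar)
  as.numeric(crossprod(matrix(cov$C, nrow = k * k), as.numeric(outer(w, w))))
}

#' SPoC_lambda decomposition
#'
#' Solves the generalized eigenproblem of (Cz, Cbar) with
#' `Cz = mean_e z(e) C(e)`; filters are normalized so `w' Cbar w = 1`, and
#' each eigenvalue equals the covariance (1/N denominator) between the
#' component's per-epoch variance and the target z, sorted from most
#' positive to most negative. The retained component is the one with the
#' smallest (most negative) lambda.
#'
#' @param cov an `epoch_covariances`
#' @param z continuous target, one value per epoch (z-scored internally)
#' @param rank_tol rank-truncation tolerance for whitening `Cbar`
#' @return object of class `spoc_result`: `filters_W`, `patterns_A`,
#'   `lambdas` (descending), `chosen_index` (smallest lambda)
#' @export
spoc_decompose <- function(cov, z, rank_tol = 1e-10) {
  stopifnot(inherits(cov, "epoch_covariances"))
  assert_that(length(z) == cov$n_epochs, "z length must equal epoch count")
  if (stats::sd(z) == 0) stop_degenerate("constant target z")
  z <- as.numeric(scale(z))
  k <- nrow(cov$Cbar)
  if (cov$n_epochs < k) stop_invalid("fewer epochs than components")
  Cz <- matrix(matrix(cov$C, nrow = k * k) %*% z / cov$n_epochs, k, k)
  P <- whitener(cov$Cbar, rank_tol)            # w' Cbar w = I by construction
  M <- t(P) %*% Cz %*% P
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  W <- P %*% e$vectors
  A <- t(MASS::ginv(W))
  structure(list(filters_W = W, patterns_A = A, lambdas = e$values,
                 chosen_index = which.min(e$values), z = z),
            class = "spoc_result")
}

#' Reconstruct the target from the chosen SPoC component
#'
#' `z_est(e) = w' C(e) w` for the chosen (smallest-lambda) filter, and its
#' Pearson correlation with the target.
#'
#' @param res a `spoc_result`
#' @param cov the `epoch_covariances` the decomposition was fitted on
#' @param component filter index; defaults to the chosen component
#' @return list with `z_est` and `r`
#' @export
estimate_target <- function(res, cov, component = res$chosen_index) {
  stopifnot(inherits(res, "spoc_result"))
  z_est <- filter_variance_series(cov, res$filters_W[, component])
  list(z_est = z_est, r = stats::cor(res$z, z_est))
}

#' Phase-randomized surrogate target
#'
#' Returns a real series with exactly the Fourier amplitude spectrum of `z`
#' (DC and Nyquist preserved, conjugate symmetry enforced) but uniformly
#' random phases, hence the same autocorrelation.
#'
#' @param z numeric target series (length >= 4)
#' @param seed optional integer seed
#' @return surrogate series, same length as `z`
#' @export
surrogate_target <- function(z, seed = NULL) {
  assert_that(length(z) >= 4, "need at least 4 samples")
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  n <- length(z)
  zf <- stats::fft(z)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  ph <- runif(half, 0, 2 * pi)
  zf[2:(half + 1)] <- Mod(zf[2:(half + 1)]) * exp(1i * ph)
  zf[n:(n - half + 1)] <- Conj(zf[2:(half + 1)])
  # DC and (for even n) Nyquist bins left untouched: both stay real and
  # keep their amplitude exactly
  Re(stats::fft(zf, inverse = TRUE)) / n
}

#' SPoC permutation test
#'
#' Each permutation re-runs the full decomposition and target estimation on
#' a fresh phase-randomized surrogate target; the p-value is the fraction
#' of permuted r values smaller than the observed one (with the +1
#' correction), matching the one-sided hypothesis of a negative
#' alpha-power/arousal correlation.
#'
#' @param cov an `epoch_covariances`
#' @param z continuous target, one value per epoch
#' @param n_perm number of permutations (>= 100)
#' @param seed integer seed
#' @return object of class `spoc_test`: observed `r`, `lambda`,
#'   `chosen_index`, `p_value`, `null_r`, plus filters/patterns
#' @export
spoc_permutation_test <- function(cov, z, n_perm = 1000, seed = 1L) {
  assert_that(n_perm >= 100, "need at least 100 permutations")
  res <- spoc_decompose(cov, z)
  obs <- estimate_target(res, cov)
  null_r <- vapply(seq_len(n_perm), function(i) {
    zp <- surrogate_target(res$z, seed = derive_seed(seed, i))
    rp <- spoc_decompose(cov, zp)
    estimate_target(rp, cov)$r
  }, numeric(1))
  structure(list(r = obs$r, z_est = obs$z_est,
                 lambda = res$lambdas[res$chosen_index],
                 lambdas = res$lambdas,
                 chosen_index = res$chosen_index,
                 filters_W = res$filters_W, patterns_A = res$patterns_A,
                 p_value = perm_pvalue(sum(null_r < obs$r), n_perm),
                 null_r = null_r),
            class = "spoc_test")
}

#' Group-level SPoC test
#'
#' One-sample, one-tailed t-test (lower tail) on per-subject differences
#' between the observed correlation and the mean of that subject's
#' permutation null: is the mean correlation significantly lower than the
#' average of the permuted ones?
#'
#' @param r_values per-subject observed correlations
#' @param null_means per-subject means of the permutation null
#' @return list with `t`, `df`, `p`
#' @export
spoc_group_test <- function(r_values, null_means) {
  assert_that(length(r_values) == length(null_means), "length mismatch")
  assert_that(length(r_values) >= 3, "need at least 3 subjects")
  d <- r_values - null_means
  if (all(d == 0))
    return(list(t = 0, df = length(d) - 1, p = 0.5))
  ht <- stats::t.test(d, alternative = "less")
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Serialize SPoC test results to JSON
#' @param test a `spoc_test`
#' @param path output file path
#' @export
spoc_to_json <- function(test, path) {
  jsonlite::write_json(list(lambdas = test$lambdas, lambda = test$lambda,
                            chosen_index = test$chosen_index, r = test$r,
                            p_value = test$p_value),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
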