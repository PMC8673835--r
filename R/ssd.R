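# Spatio-spectral decomposition: generalized eigenvalue contrast of
# alpha-band covariance against flanking-band covariance, plus the
# two-criterion spectral component-selection rule.

# Whitening matrix from an eigendecomposition with rank truncation at
# eigenvalue ratio `tol` of the largest (guards rank deficiency).
whitener <- function(C, tol = 1e-10) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  if (sum(keep) < 2) stop_degenerate("covariance rank < 2 after truncation")
  e$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(e$values[keep]),
                                           nrow = sum(keep))
}

#' Spatio-spectral decomposition of a recording
#'
#' Band-passes the data in the signal band (alpha peak +/- 2 Hz) and in the
#' noise band (+/- 4 Hz with the +/- 3 Hz stop band removed), and solves the
#' generalized eigenproblem maximizing `w' Cs w / w' Cn w` after
#' rank-truncating whitening of the noise covariance. Components are the
#' filter projections; spatial patterns come from inverting the (possibly
#' rank-restricted) filter matrix.
#'
#' @param rec an `eeg_recording` (>= 2 channels, >= 10 s)
#' @param bands band list from [ssd_bands()]
#' @param rank_tol eigenvalue-ratio threshold for rank truncation
#' @return object of class `ssd_result`: `filters_W`, `patterns_A`
#'   (channels x components), `eigenvalues` (descending signal/noise power
#'   ratios), `components` (components x samples, broadband projections for
#'   spectral inspection), `components_signal` (signal-band projections,
#'   the decoder input), `fs`, `bands`
#' @export
ssd_decompose <- function(rec, bands, rank_tol = 1e-10) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_that(nrow(rec$data) >= 2, "need at least 2 channels")
  assert_that(ncol(rec$data) >= 10 * rec$fs, "need at least 10 s of data")
  X <- t(rec$data)                             # samples x channels
  Xs <- bandpass_filter(X, bands$signal, rec$fs)
  Xn <- bandstop_filter(bandpass_filter(X, bands$noise, rec$fs),
                        bands$stop, rec$fs)
  Cs <- stats::cov(Xs)
  Cn <- stats::cov(Xn)
  P <- whitener(Cn, rank_tol)
  M <- t(P) %*% Cs %*% P
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  W <- P %*% e$vectors                         # channels x components
  A <- t(MASS::ginv(W))                        # invert the filter matrix
  rownames(W) <- rownames(A) <- rec$channel_labels
  structure(list(filters_W = W, patterns_A = A, eigenvalues = e$values,
                 components = t(X %*% W), components_signal = t(Xs %*% W),
                 fs = rec$fs, bands = bands),
            class = "ssd_result")
}

# Detrended component spectrum used by the selection rule: Welch PSD of the
# broadband projection, aperiodic fit excluding alpha_peak +/- 4 Hz.
component_detrended_spectrum <- function(comp, fs, alpha_peak_hz,
                                         fit_range = c(0, 40)) {
  spec <- welch_psd(comp, fs)
  fit <- fit_one_over_f(spec, exclusion_center_hz = alpha_peak_hz,
                        range_hz = fit_range)
  detrend_spectrum(spec, fit)
}

#' Select SSD components with a clear alpha peak
#'
#' A component is kept iff, on its detrended (natural-log residual)
#' spectrum, (A) the peak inside the alpha window (peak +/- 2 Hz) exceeds
#' `threshold`, and (B) after z-scoring the detrended spectrum over the fit
#' range, the alpha-window peak exceeds the larger of the two adjacent
#' 2-Hz flank means by at least `flank_sd`.
#'
#' @param res an `ssd_result`
#' @param alpha_peak_hz individual alpha peak in Hz
#' @param threshold criterion-A decision threshold on the log-residual scale
#' @param flank_sd criterion-B margin, in SD units of the z-scored residuals
#' @param flank_width_hz flank width in Hz
#' @param fit_range aperiodic fit (and z-scoring) range in Hz
#' @return integer vector of selected component indices
#' @export
select_components <- function(res, alpha_peak_hz, threshold = 0.35,
                              flank_sd = 1.45, flank_width_hz = 2,
                              fit_range = c(0, 40)) {
  stopifnot(inherits(res, "ssd_result"))
  win <- c(alpha_peak_hz - 2, alpha_peak_hz + 2)
  need <- c(alpha_peak_hz - 2 - flank_width_hz,
            alpha_peak_hz + 2 + flank_width_hz)
  keep <- logical(nrow(res$components))
  for (k in seq_along(keep)) {
    det <- component_detrended_spectrum(res$components[k, ], res$fs,
                                        alpha_peak_hz, fit_range)
    if (min(det$freqs) > need[1] || max(det$freqs) < need[2])
      stop_invalid("component spectrum does not cover the flank bands")
    inwin <- det$freqs >= win[1] & det$freqs <= win[2]
    crit_a <- max(det$residual[inwin]) > threshold
    z <- (det$residual - mean(det$residual)) / stats::sd(det$residual)
    lo <- det$freqs >= need[1] & det$freqs < win[1]
    hi <- det$freqs > win[2] & det$freqs <= need[2]
    crit_b <- max(z[inwin]) - max(mean(z[lo]), mean(z[hi])) >= flank_sd
    keep[k] <- crit_a && crit_b
  }
  which(keep)
}

#' Minimum-component rule for subject inclusion
#'
#' Decoders are trained only on subjects with at least `minimum` selected
#' SSD components.
#'
#' @param selected integer vector of selected component indices
#' @param minimum minimum count
#' @return `TRUE` if the subject is kept
#' @export
require_min_components <- function(selected, minimum = 4) {
  length(selected) >= minimum
}
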