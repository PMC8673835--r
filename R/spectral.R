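# Welch spectra, aperiodic 1/f fit, spectral detrending, individual
# alpha-peak detection and SSD band construction.

#' Welch power spectral density
#'
#' Averaged Hann-windowed periodograms (density scaling, uV^2/Hz) over
#' segments of `segment_s` seconds with fractional `overlap`.
#'
#' @param x numeric signal
#' @param fs sampling rate in Hz
#' @param segment_s segment length in seconds
#' @param overlap overlap fraction in \[0, 1)
#' @return object of class `psd_spectrum` with `freqs` (Hz) and `power`
#' @export
welch_psd <- function(x, fs, segment_s = 5, overlap = 0.5) {
  nper <- round(segment_s * fs)
  if (length(x) < nper) stop_invalid("signal shorter than one Welch segment")
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  scale <- fs * sum(w^2)
  nf <- nper %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg)[seq_len(nf)])^2 / scale
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]      # one-sided
    if (nper %% 2 == 1) p[nf] <- 2 * p[nf]
    acc <- acc + p
  }
  structure(list(freqs = (seq_len(nf) - 1) * fs / nper,
                 power = acc / length(starts), fs = fs,
                 welch_segment_s = segment_s, overlap_fraction = overlap),
            class = "psd_spectrum")
}

#' Aperiodic 1/f fit of a power spectrum
#'
#' Least-squares line in (log f, log p) space over `range_hz`, excluding a
#' window of `exclusion_halfwidth_hz` around `exclusion_center_hz` (the
#' candidate alpha peak) and the zero-frequency bin. The fitted model is
#' `log p = -log a - b log f`, with stretch `a > 0` and slope `b`.
#'
#' @param spec a `psd_spectrum`
#' @param exclusion_center_hz centre of the excluded oscillatory window
#' @param exclusion_halfwidth_hz half-width of the excluded window (Hz)
#' @param range_hz fit range (Hz)
#' @return object of class `one_over_f_fit` with `a`, `b` and bookkeeping
#' @export
fit_one_over_f <- function(spec, exclusion_center_hz,
                           exclusion_halfwidth_hz = 4, range_hz = c(0, 40)) {
  f <- spec$freqs; p <- spec$power
  sel <- f > 0 & f >= range_hz[1] & f <= range_hz[2] &
    abs(f - exclusion_center_hz) > exclusion_halfwidth_hz
  if (sum(sel) < 5) stop_invalid("fewer than 5 bins left for the 1/f fit")
  if (all(p[sel] <= 0)) stop_invalid("all-zero power in fit range")
  sel <- sel & p > 0
  fit <- stats::lm(log(p[sel]) ~ log(f[sel]))
  b <- -unname(coef(fit)[2])
  a <- exp(-unname(coef(fit)[1]))
  structure(list(a = a, b = b, fit_range_hz = range_hz,
                 exclusion_center_hz = exclusion_center_hz,
                 exclusion_halfwidth_hz = exclusion_halfwidth_hz),
            class = "one_over_f_fit")
}

# Fitted log-power curve on a frequency grid (natural log).
one_over_f_curve <- function(fit, freqs) -log(fit$a) - fit$b * log(freqs)

#' Detrend a spectrum against its aperiodic fit
#'
#' @param spec a `psd_spectrum`
#' @param fit a `one_over_f_fit` estimated on the same grid
#' @return data.frame with `freqs` and `residual` (log power minus fitted
#'   curve) over the positive-frequency grid
#' @export
detrend_spectrum <- function(spec, fit) {
  stopifnot(inherits(spec, "psd_spectrum"), inherits(fit, "one_over_f_fit"))
  sel <- spec$freqs > 0 & spec$power > 0
  data.frame(freqs = spec$freqs[sel],
             residual = log(spec$power[sel]) -
               one_over_f_curve(fit, spec$freqs[sel]))
}

#' Individual alpha peak from a detrended spectrum
#'
#' The frequency of the maximal detrended residual in `search_range`
#' (boundary argmax allowed; no minimum peak amplitude is imposed, but a
#' low-prominence peak triggers a warning).
#'
#' @param detrended data.frame from [detrend_spectrum()]
#' @param search_range frequency range searched, in Hz
#' @return alpha peak frequency in Hz
#' @export
find_alpha_peak <- function(detrended, search_range = c(8, 13)) {
  sel <- detrended$freqs >= search_range[1] & detrended$freqs <= search_range[2]
  if (!any(sel)) stop_invalid("search range contains no frequency bins")
  res <- detrended$residual[sel]
  peak <- detrended$freqs[sel][which.max(res)]
  if (max(res) < 0.05)
    warning("low-prominence alpha peak (max residual ",
            signif(max(res), 3), ")")
  peak
}

#' SSD analysis bands around an individual alpha peak
#'
#' @param alpha_peak_hz individual alpha peak in \[8, 13\] Hz
#' @return list with `signal` (peak +/- 2 Hz), `stop` (+/- 3 Hz) and
#'   `noise` (+/- 4 Hz) band edges
#' @export
ssd_bands <- function(alpha_peak_hz) {
  assert_that(alpha_peak_hz >= 8 && alpha_peak_hz <= 13,
              "alpha peak must lie in [8, 13] Hz")
  list(signal = c(alpha_peak_hz - 2, alpha_peak_hz + 2),
       stop   = c(alpha_peak_hz - 3, alpha_peak_hz + 3),
       noise  = c(alpha_peak_hz - 4, alpha_peak_hz + 4))
}

#' Detect the individual alpha peak of a multichannel recording
#'
#' Channel-mean Welch PSD, aperiodic fit (with the exclusion window centred
#' on the provisional in-range argmax of the raw log spectrum), detrending,
#' then the detrended argmax in the search range.
#'
#' @param rec an `eeg_recording`
#' @param search_range alpha search range in Hz
#' @return list with `alpha_peak_hz`, the channel-mean `spectrum`, the
#'   aperiodic `fit` and the `detrended` residual spectrum
#' @export
detect_alpha_peak <- function(rec, search_range = c(8, 13)) {
  stopifnot(inherits(rec, "eeg_recording"))
  specs <- apply(rec$data, 1, welch_psd, fs = rec$fs, simplify = FALSE)
  pow <- rowMeans(vapply(specs, function(s) s$power,
                         numeric(length(specs[[1]]$power))))
  spec <- specs[[1]]; spec$power <- pow
  inr <- spec$freqs >= search_range[1] & spec$freqs <= search_range[2]
  provisional <- spec$freqs[inr][which.max(spec$power[inr])]
  fit <- fit_one_over_f(spec, exclusion_center_hz = provisional)
  det <- detrend_spectrum(spec, fit)
  list(alpha_peak_hz = find_alpha_peak(det, search_range),
       spectrum = spec, fit = fit, detrended = det)
}

#' Write a spectrum (and optional residuals) to CSV
#' @param spec a `psd_spectrum`
#' @param path output file path
#' @param detrended optional data.frame from [detrend_spectrum()]
#' @export
spectrum_to_csv <- function(spec, path, detrended = NULL) {
  df <- data.frame(freq = spec$freqs, power = spec$power)
  if (!is.null(detrended))
    df$residual <- detrended$residual[match(df$freq, detrended$freqs)]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
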