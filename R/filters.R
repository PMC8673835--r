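# Zero-phase windowed-sinc FIR filtering.
#
# Filters are linear-phase (symmetric) Hamming-windowed sinc designs from
# signal::fir1; applying them by FFT convolution and discarding the exact
# integer group delay gives a one-pass zero-phase filter, the same family
# used for the EEG detrending stage (Hamming windowed zero-phase sinc FIR,
# 1 Hz transition band).

# Filter order for a Hamming window given the transition width in Hz.
# Rounded up to the next even number so the group delay is integer.
fir_order <- function(fs, transition_hz = 1) {
  n <- ceiling(3.3 * fs / transition_hz)
  if (n %% 2 == 1) n <- n + 1
  as.integer(n)
}

design_bandpass <- function(band, fs, transition_hz = 1) {
  assert_that(band[1] > 0 && band[2] < fs / 2, "band edges must lie in (0, fs/2)")
  signal::fir1(fir_order(fs, transition_hz), band / (fs / 2), type = "pass")
}

design_bandstop <- function(band, fs, transition_hz = 1) {
  assert_that(band[1] > 0 && band[2] < fs / 2, "band edges must lie in (0, fs/2)")
  signal::fir1(fir_order(fs, transition_hz), band / (fs / 2), type = "stop")
}

# Apply a symmetric odd-length FIR to each column of x (samples x channels)
# with zero phase: reflect-pad by the group delay, FFT convolution, trim.
fir_apply <- function(x, h) {
  x <- as.matrix(x)
  n <- nrow(x)
  L <- length(h)
  d <- (L - 1L) %/% 2L
  assert_that(L %% 2 == 1, "FIR kernel must have odd length (even order)")
  assert_that(n > d, "signal shorter than filter group delay")
  pad_top <- x[seq(d + 1L, 2L), , drop = FALSE]
  pad_bot <- x[seq(n - 1L, n - d), , drop = FALSE]
  xp <- rbind(pad_top, x, pad_bot)
  np <- nrow(xp)
  nfft <- stats::nextn(np + L - 1L, c(2, 3, 5))
  Hf <- stats::fft(c(h, numeric(nfft - L)))
  Xf <- stats::mvfft(rbind(xp, matrix(0, nfft - np, ncol(xp))))
  y <- Re(stats::mvfft(Xf * Hf, inverse = TRUE)) / nfft
  # full convolution peak-aligned: drop group delay then the reflection pads
  y[seq(2L * d + 1L, 2L * d + n), , drop = FALSE]
}

#' Zero-phase band-pass filter
#'
#' Hamming-windowed sinc FIR (1 Hz transition band by default), applied
#' with zero phase via delay-compensated FFT convolution.
#'
#' @param x numeric vector or samples-by-channels matrix
#' @param band length-2 numeric, band edges in Hz
#' @param fs sampling rate in Hz
#' @param transition_hz transition band width in Hz
#' @return filtered data, same shape as `x`
#' @export
bandpass_filter <- function(x, band, fs, transition_hz = 1) {
  vec <- is.null(dim(x))
  y <- fir_apply(as.matrix(x), design_bandpass(band, fs, transition_hz))
  if (vec) drop(y) else y
}

#' Zero-phase band-stop filter
#' @inheritParams bandpass_filter
#' @return filtered data, same shape as `x`
#' @export
bandstop_filter <- function(x, band, fs, transition_hz = 1) {
  vec <- is.null(dim(x))
  y <- fir_apply(as.matrix(x), design_bandstop(band, fs, transition_hz))
  if (vec) drop(y) else y
}
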