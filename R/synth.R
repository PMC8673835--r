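# Synthetic-data generator: ground-truth-known multichannel EEG plus a
# continuous arousal rating trace, emulating a 270-s immersive experience
# (ride - break - ride) recorded from 30 scalp channels at 250 Hz.

# 30-channel 10-20 montage used throughout; posterior set drives the
# parieto-occipital emphasis of alpha-source patterns.
eeg_channel_labels <- function(n_channels = 30) {
  labs <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
            "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
            "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
            "PO9", "O1", "Oz", "O2", "PO10")
  if (n_channels <= length(labs)) labs[seq_len(n_channels)]
  else c(labs, paste0("EXT", seq_len(n_channels - length(labs))))
}

posterior_channels <- function() {
  c("CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
    "PO9", "O1", "Oz", "O2", "PO10")
}

#' Configuration for the synthetic EEG + arousal generator
#'
#' Defaults encode the emulated study conditions: a 270-s experience split
#' into two rides (148 s, 92 s) around a 30-s break, 30 channels at 250 Hz,
#' a narrowband individual-alpha source whose amplitude envelope is
#' negatively coupled to the arousal trace, uncoupled distractor alpha
#' sources, 1/f aperiodic background sources, and white sensor noise.
#'
#' @param n_channels number of scalp channels
#' @param fs sampling rate in Hz
#' @param duration_s total duration in seconds
#' @param segment_lengths_s lengths (s) of ride1, break, ride2; must sum to
#'   `duration_s`
#' @param alpha_peak_hz individual alpha peak frequency in \[8, 13\] Hz
#' @param coupling_kappa envelope-arousal coupling strength in \[0, 1\];
#'   0 is the null model
#' @param n_alpha_sources number of narrowband alpha sources (the first is
#'   the arousal-coupled one; the rest are uncoupled distractors)
#' @param n_background_sources number of 1/f aperiodic background sources
#' @param aperiodic_slope spectral slope b of the 1/f^b backgrounds
#' @param alpha_amp_uv baseline alpha source amplitude scale (uV)
#' @param background_amp_uv background source amplitude scale (uV)
#' @param sensor_noise_sd white sensor noise SD (uV)
#' @param rating_smooth_s smoothing bandwidth (s) of the arousal random walk
#' @param seed integer seed; generation is bit-reproducible given the config
#' @return object of class `synth_config`
#' @export
synth_config <- function(n_channels = 30, fs = 250, duration_s = 270,
                         segment_lengths_s = c(148, 30, 92),
                         alpha_peak_hz = 10, coupling_kappa = 0.8,
                         n_alpha_sources = 4, n_background_sources = 8,
                         aperiodic_slope = 1.5,
                         alpha_amp_uv = 8, background_amp_uv = 12,
                         sensor_noise_sd = 1, rating_smooth_s = 8,
                         seed = 1L) {
  assert_that(n_channels >= 2, "need at least 2 channels")
  assert_that(duration_s > 0, "duration must be positive")
  assert_that(length(segment_lengths_s) == 3 &&
                sum(segment_lengths_s) == duration_s,
              "segment lengths must sum to duration_s")
  assert_that(alpha_peak_hz >= 8 && alpha_peak_hz <= 13,
              "alpha peak must lie in [8, 13] Hz")
  assert_that(coupling_kappa >= 0 && coupling_kappa <= 1,
              "coupling_kappa must lie in [0, 1]")
  assert_that(fs > 2 * (alpha_peak_hz + 4),
              "fs too low for the alpha noise band (need fs > 2*(peak+4))")
  assert_that(n_alpha_sources >= 1, "need at least the coupled alpha source")
  structure(list(n_channels = n_channels, fs = fs, duration_s = duration_s,
                 segment_lengths_s = segment_lengths_s,
                 alpha_peak_hz = alpha_peak_hz,
                 coupling_kappa = coupling_kappa,
                 n_alpha_sources = n_alpha_sources,
                 n_background_sources = n_background_sources,
                 aperiodic_slope = aperiodic_slope,
                 alpha_amp_uv = alpha_amp_uv,
                 background_amp_uv = background_amp_uv,
                 sensor_noise_sd = sensor_noise_sd,
                 rating_smooth_s = rating_smooth_s,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Gaussian smoothing with edge renormalization (kernel mass inside the
# signal support always sums to one).
gauss_smooth <- function(x, bw) {
  if (bw <= 0) return(x)
  half <- max(1L, ceiling(3 * bw))
  k <- exp(-0.5 * ((-half):half / bw)^2)
  n <- length(x)
  num <- stats::convolve(x, rev(k), type = "open")
  den <- stats::convolve(rep(1, n), rev(k), type = "open")
  (num / den)[(half + 1):(half + n)]
}

#' Generate a quantized continuous arousal rating trace
#'
#' A smoothed Gaussian random walk with per-phase offsets (rides high,
#' break low), clipped to \[0, 100\] and quantized to an `n_levels`-point
#' dial grid, one value per second.
#'
#' @param duration_s trace length in seconds (>= 30)
#' @param n_levels number of discrete dial levels (>= 2)
#' @param phase_profile list with `lengths_s` (segment lengths, summing to
#'   `duration_s`), `offsets` (per-phase mean levels) and `noise_sd`
#'   (SD of the smoothed walk; 0 gives a deterministic trace)
#' @param smooth_s smoothing bandwidth of the walk, in seconds
#' @param seed integer seed
#' @return object of class `rating_trace` with fields `values` (dial grid),
#'   `n_levels`, and `z` (z-scored values, the regression target)
#' @export
generate_arousal_trace <- function(duration_s = 270, n_levels = 50,
                                   phase_profile = NULL,
                                   smooth_s = 8, seed = 1L) {
  if (duration_s < 30) stop_invalid("duration_s must be >= 30")
  assert_that(n_levels >= 2, "need at least 2 rating levels")
  if (is.null(phase_profile)) {
    # default ride/break/ride proportions of the 148/30/92 s experience
    l1 <- round(duration_s * 148 / 270)
    l2 <- round(duration_s * 30 / 270)
    phase_profile <- list(lengths_s = c(l1, l2, duration_s - l1 - l2),
                          offsets = c(52, 20, 62), noise_sd = 14)
  }
  assert_that(sum(phase_profile$lengths_s) == duration_s,
              "phase lengths must sum to duration_s")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  walk <- gauss_smooth(cumsum(rnorm(duration_s)), smooth_s)
  if (stats::sd(walk) > 0)
    walk <- walk / stats::sd(walk) * phase_profile$noise_sd
  offsets <- rep(phase_profile$offsets, times = phase_profile$lengths_s)
  # soften phase transitions so the dial does not jump instantaneously
  offsets <- gauss_smooth(offsets, 2)
  raw <- pmin(100, pmax(0, walk - mean(walk) + offsets))
  grid <- seq(0, 100, length.out = n_levels)
  values <- grid[apply(abs(outer(raw, grid, "-")), 1, which.min)]
  new_rating_trace(values, n_levels)
}

new_rating_trace <- function(values, n_levels = 50) {
  z <- if (length(values) > 1 && stats::sd(values) > 0)
    as.numeric(scale(values)) else values * 0
  structure(list(values = values, n_levels = n_levels, z = z),
            class = "rating_trace")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# 1/f^slope noise of length n, unit SD, via FFT amplitude shaping of white
# Gaussian noise (uses the current RNG stream).
one_over_f_noise <- function(n, fs, slope) {
  x <- rnorm(n)
  xf <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]          # fold to physical frequency
  g <- c(0, (f[-1])^(-slope / 2))              # kill DC, shape power ~ 1/f^b
  y <- Re(stats::fft(xf * g, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Narrowband source at peak_hz +/- 2 Hz, unit SD (current RNG stream).
narrowband_source <- function(n, fs, peak_hz) {
  y <- bandpass_filter(rnorm(n), c(peak_hz - 2, peak_hz + 2), fs)
  y / stats::sd(y)
}

# Smoothed random spatial pattern; posterior emphasis concentrates weight
# over parieto-occipital channels. Unit-norm column.
random_pattern <- function(labels, posterior_emphasis = FALSE) {
  n <- length(labels)
  w <- gauss_smooth(rnorm(n), 1.5)
  if (posterior_emphasis) {
    emph <- ifelse(labels %in% posterior_channels(), 1, 0.25)
    w <- (abs(w) + 0.3) * sign(w + 1e-12) * emph
  }
  w / sqrt(sum(w^2))
}

#' Generate one synthetic subject
#'
#' Builds the full generative model: an arousal trace, one narrowband alpha
#' source whose per-second amplitude envelope scales as
#' `baseline * (1 - kappa * z01(t))` (z01 = trace min-max normalized to
#' \[0, 1\]), uncoupled distractor alpha sources with independent slow
#' envelopes, 1/f^b aperiodic background sources, spatial mixing into the
#' sensors, and additive white sensor noise.
#'
#' @param config a [synth_config()]
#' @return list with elements `recording` (class `eeg_recording`: `data`
#'   channels x samples in uV, `fs`, `channel_labels`, `segment_marks`
#'   0-based half-open sample boundaries), `trace` (class `rating_trace`),
#'   and `ground_truth` (mixing matrix, coupled-source index and pattern,
#'   per-second source envelope, kappa)
#' @export
generate_subject <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 1L))
  trace <- generate_arousal_trace(
    duration_s = config$duration_s,
    phase_profile = list(lengths_s = config$segment_lengths_s,
                         offsets = c(52, 20, 62), noise_sd = 14),
    smooth_s = config$rating_smooth_s,
    seed = derive_seed(config$seed, 2L))
  set.seed(derive_seed(config$seed, 3L))

  fs <- config$fs
  n <- config$duration_s * fs
  labels <- eeg_channel_labels(config$n_channels)
  n_src <- config$n_alpha_sources + config$n_background_sources

  # per-second envelope of the coupled source, interpolated to sample rate
  rng <- range(trace$values)
  z01 <- if (diff(rng) > 0) (trace$values - rng[1]) / diff(rng)
         else rep(0.5, length(trace$values))
  env_sec <- 1 - config$coupling_kappa * z01
  sec_centers <- (seq_len(config$duration_s) - 0.5) * fs
  env_samp <- stats::approx(sec_centers, env_sec, xout = seq_len(n),
                            rule = 2)$y

  S <- matrix(0, n, n_src)
  S[, 1] <- narrowband_source(n, fs, config$alpha_peak_hz) * env_samp *
    config$alpha_amp_uv
  if (config$n_alpha_sources > 1) {
    # distractors are amplitude-stationary: any slow envelope modulation
    # would correlate spuriously with the (slow) arousal trace over 270 s
    # and contaminate the kappa = 0 null model
    jitter <- seq(-0.5, 0.5, length.out = config$n_alpha_sources)[-1]
    for (j in seq_len(config$n_alpha_sources - 1)) {
      S[, 1 + j] <- narrowband_source(n, fs, config$alpha_peak_hz + jitter[j]) *
        config$alpha_amp_uv * 0.8
    }
  }
  for (j in seq_len(config$n_background_sources)) {
    S[, config$n_alpha_sources + j] <-
      one_over_f_noise(n, fs, config$aperiodic_slope) * config$background_amp_uv
  }

  A <- sapply(seq_len(n_src), function(j)
    random_pattern(labels, posterior_emphasis = j <= config$n_alpha_sources))
  X <- A %*% t(S) + matrix(rnorm(config$n_channels * n,
                                 sd = config$sensor_noise_sd),
                           config$n_channels, n)
  rownames(X) <- labels

  marks <- c(0, cumsum(config$segment_lengths_s)) * fs
  recording <- new_recording(X, fs, labels, marks, cropped = TRUE)
  gt <- structure(list(mixing_matrix = A, arousal_source_index = 1L,
                       alpha_pattern = A[, 1],
                       source_envelope = env_sec,
                       coupling_kappa = config$coupling_kappa,
                       sources = S),
                  class = "ground_truth")
  list(recording = recording, trace = trace, ground_truth = gt)
}

new_recording <- function(data, fs, channel_labels, segment_marks,
                          cropped = FALSE) {
  data <- as.matrix(data)
  assert_that(all(diff(segment_marks) > 0) &&
                segment_marks[1] >= 0 &&
                segment_marks[length(segment_marks)] <= ncol(data),
              "segment marks must be strictly increasing and within bounds")
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 segment_marks = as.numeric(segment_marks)),
            class = "eeg_recording", cropped = cropped)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Cosine similarity between two spatial patterns
#'
#' Invariant (up to sign) to rescaling of either vector; used as the
#' recovery metric between estimated and planted scalp patterns.
#'
#' @param a,b equal-length numeric channel weight vectors
#' @return cosine similarity in \[-1, 1\]
#' @export
pattern_similarity <- function(a, b) {
  assert_that(length(a) == length(b), "patterns must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop_invalid("zero-norm pattern")
  sum(a * b) / (na * nb)
}

#' Write a rating trace to CSV (columns: second, rating)
#' @param trace a `rating_trace`
#' @param path output file path
#' @export
rating_to_csv <- function(trace, path) {
  utils::write.csv(data.frame(second = seq_along(trace$values) - 1L,
                              rating = trace$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write generator ground truth to JSON
#' @param gt a `ground_truth`
#' @param path output file path
#' @export
ground_truth_to_json <- function(gt, path) {
  jsonlite::write_json(list(
    mixing_matrix = gt$mixing_matrix,
    arousal_source_index = gt$arousal_source_index,
    alpha_pattern = gt$alpha_pattern,
    source_envelope = gt$source_envelope,
    coupling_kappa = gt$coupling_kappa), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
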