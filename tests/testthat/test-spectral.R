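# Welch spectra, aperiodic 1/f fits, detrending, alpha-peak detection.

make_spectrum <- function(freqs, power, fs = 250) {
  structure(list(freqs = freqs, power = power, fs = fs,
                 welch_segment_s = 5, overlap_fraction = 0.5),
            class = "psd_spectrum")
}

test_that("welch_psd localizes a pure tone and conserves variance", {
  fs <- 250
  t <- seq_len(60 * fs) / fs
  spec <- welch_psd(sin(2 * pi * 10 * t), fs)
  expect_equal(spec$freqs[which.max(spec$power)], 10)
  expect_equal(diff(spec$freqs)[1], 0.2)
  # Parseval: integrated density matches signal variance for broadband noise
  set.seed(1)
  x <- rnorm(120 * fs)
  spec <- welch_psd(x, fs)
  expect_lt(abs(sum(spec$power) * 0.2 - var(x)) / var(x), 0.05)
  expect_error(welch_psd(rnorm(100), fs), "shorter")
})

test_that("welch_psd of white noise is flat within 3 MADs", {
  # oracle: long-run average over many draws approaches a constant level
  fs <- 250
  acc <- 0
  set.seed(42)
  for (i in 1:100) acc <- acc + welch_psd(rnorm(20 * fs), fs)$power
  # interior bins only: DC and its neighbour are notched by per-segment
  # demeaning, and the one-sided convention halves the Nyquist bin
  p <- (acc / 100)[3:(length(acc) - 1)]
  expect_lt(max(abs(p - median(p))), 3 * mad(p) + 1e-12)
})

test_that("1/f fit recovers exact power-law parameters", {
  f <- seq(0.2, 40, by = 0.2)
  fit <- fit_one_over_f(make_spectrum(f, 1 / f), exclusion_center_hz = 10)
  expect_equal(fit$a, 1, tolerance = 1e-10)
  expect_equal(fit$b, 1, tolerance = 1e-10)
  flat <- fit_one_over_f(make_spectrum(f, rep(4, length(f))),
                         exclusion_center_hz = 10)
  expect_equal(flat$b, 0, tolerance = 1e-10)
  expect_equal(flat$a, 1 / 4, tolerance = 1e-10)
})

test_that("a bump inside the exclusion window leaves the fit unchanged", {
  f <- seq(0.2, 40, by = 0.2)
  clean <- 2.5 / f^1.3
  bump <- clean + 3 * exp(-(f - 10)^2 / 0.5)  # tails < 1e-13 beyond +/- 4
  fit_clean <- fit_one_over_f(make_spectrum(f, clean), 10)
  fit_bump <- fit_one_over_f(make_spectrum(f, bump), 10)
  expect_equal(fit_bump$a, fit_clean$a, tolerance = 1e-9)
  expect_equal(fit_bump$b, fit_clean$b, tolerance = 1e-9)
})

test_that("1/f fit is scale-equivariant", {
  f <- seq(0.2, 40, by = 0.2)
  set.seed(3)
  p <- (2 / f^1.1) * exp(rnorm(length(f), sd = 0.1))
  f1 <- fit_one_over_f(make_spectrum(f, p), 10)
  f2 <- fit_one_over_f(make_spectrum(f, 7 * p), 10)
  expect_equal(f2$b, f1$b, tolerance = 1e-9)
  expect_equal(f2$a, f1$a / 7, tolerance = 1e-9)
})

test_that("detrending flattens pure 1/f and exposes oscillatory bumps", {
  f <- seq(0.2, 40, by = 0.2)
  spec <- make_spectrum(f, 3 / f^1.5)
  fit <- fit_one_over_f(spec, 10)
  det <- detrend_spectrum(spec, fit)
  expect_lt(max(abs(det$residual)), 1e-6)
  bumped <- make_spectrum(f, 3 / f^1.5 + 2 * exp(-(f - 10)^2 / 0.5))
  det_b <- detrend_spectrum(bumped, fit_one_over_f(bumped, 10))
  expect_equal(det_b$freqs[which.max(det_b$residual)], 10, tolerance = 0.21)
  # a global power rescaling is absorbed by refitting
  doubled <- make_spectrum(f, 2 * bumped$power)
  det_d <- detrend_spectrum(doubled, fit_one_over_f(doubled, 10))
  expect_equal(det_d$residual, det_b$residual, tolerance = 1e-9)
})

test_that("alpha peak is the in-range detrended argmax", {
  f <- seq(0.2, 40, by = 0.2)
  res <- exp(-(f - 10)^2 / 0.5)
  expect_equal(find_alpha_peak(data.frame(freqs = f, residual = res)), 10)
  two <- exp(-(f - 9)^2 / 0.2) + 1.5 * exp(-(f - 12)^2 / 0.2)
  expect_equal(find_alpha_peak(data.frame(freqs = f, residual = two)), 12)
  expect_warning(
    mono <- find_alpha_peak(data.frame(freqs = f, residual = -f / 40)),
    "low-prominence")
  expect_equal(mono, 8)    # boundary argmax
  # invariant under monotone rescaling of residuals
  expect_equal(find_alpha_peak(data.frame(freqs = f, residual = exp(two))),
               find_alpha_peak(data.frame(freqs = f, residual = two)))
  expect_error(find_alpha_peak(data.frame(freqs = f, residual = res),
                               search_range = c(45, 50)), "no frequency")
})

test_that("SSD bands follow the +/- 2/3/4 Hz construction", {
  b <- ssd_bands(10)
  expect_equal(b$signal, c(8, 12))
  expect_equal(b$stop, c(7, 13))
  expect_equal(b$noise, c(6, 14))
  expect_equal(ssd_bands(8)$signal, c(6, 10))
  expect_equal(ssd_bands(13)$noise, c(9, 17))
  expect_error(ssd_bands(7.5), "8")
})

test_that("zero-phase band filters pass the band without phase shift", {
  fs <- 250
  t <- seq_len(30 * fs) / fs
  s10 <- sin(2 * pi * 10 * t)
  s20 <- sin(2 * pi * 20 * t)
  y <- bandpass_filter(s10 + s20, c(8, 12), fs)
  core <- 1000:6500
  expect_gt(cor(y[core], s10[core]), 0.999)            # in-band, in phase
  expect_lt(var(bandpass_filter(s20, c(8, 12), fs)[core]), 1e-4)
  ystop <- bandstop_filter(s10 + s20, c(8, 12), fs)
  expect_gt(cor(ystop[core], s20[core]), 0.999)
})
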