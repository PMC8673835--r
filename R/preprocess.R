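# Deterministic data conditioning: cropping, rating resampling, epoch
# screening, subject exclusion, epoching and tertile labelling.

#' Crop a recording to the analysed experience
#'
#' On raw input, removes the first and last `ride_trim_s` seconds of each
#' ride and centre-crops the break to `break_length_s`, yielding the
#' analysed experience (270 s under the study defaults). On already-cropped
#' input the trims are skipped (idempotent). With `include_break = FALSE`
#' the break segment is dropped entirely (240 s under the defaults).
#'
#' @param rec an `eeg_recording` whose `segment_marks` delimit
#'   ride1 / break / ride2 (0-based, half-open)
#' @param include_break keep the break segment?
#' @param ride_trim_s seconds trimmed from each end of each ride (raw input)
#' @param break_length_s target break length in seconds (raw input)
#' @return cropped `eeg_recording` with updated `segment_marks`
#' @export
crop_experience <- function(rec, include_break = TRUE,
                            ride_trim_s = 2.5, break_length_s = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_that(length(rec$segment_marks) == 4,
              "segment_marks must delimit ride1/break/ride2")
  fs <- rec$fs
  m <- rec$segment_marks
  already <- isTRUE(attr(rec, "cropped"))
  segs <- lapply(1:3, function(k) c(m[k], m[k + 1]))
  seg_len <- vapply(segs, diff, numeric(1)) / fs
  if (any(seg_len[c(1, 3)] <= if (already) 0 else 2 * ride_trim_s))
    stop_invalid("ride segment too short to crop")
  if (!already) {
    trim <- ride_trim_s * fs
    segs[[1]] <- c(segs[[1]][1] + trim, segs[[1]][2] - trim)
    segs[[3]] <- c(segs[[3]][1] + trim, segs[[3]][2] - trim)
    bl <- diff(segs[[2]])
    target <- break_length_s * fs
    if (bl < target) stop_invalid("break shorter than target length")
    off <- floor((bl - target) / 2)
    segs[[2]] <- c(segs[[2]][1] + off, segs[[2]][1] + off + target)
  }
  keep <- if (include_break) segs else segs[c(1, 3)]
  idx <- unlist(lapply(keep, function(s) seq(s[1] + 1, s[2])))
  lens <- vapply(keep, diff, numeric(1))
  new_recording(rec$data[, idx, drop = FALSE], fs, rec$channel_labels,
                c(0, cumsum(lens)), cropped = TRUE)
}

#' Resample a dial-rate rating series to 1 Hz
#'
#' Averages non-overlapping windows of `rate_hz` samples (one per second);
#' a trailing partial window is dropped with a message.
#'
#' @param raw numeric rating series sampled at `rate_hz`
#' @param rate_hz native dial sampling rate (50 Hz in the emulated study)
#' @param n_levels dial grid size carried into the result
#' @return a `rating_trace` with one value per second
#' @export
resample_ratings <- function(raw, rate_hz = 50, n_levels = 50) {
  if (length(raw) == 0) stop_invalid("empty rating series")
  n_sec <- length(raw) %/% rate_hz
  if (n_sec == 0) stop_invalid("rating series shorter than one second")
  if (length(raw) %% rate_hz != 0)
    message("dropping trailing partial window of ",
            length(raw) %% rate_hz, " samples")
  m <- matrix(raw[seq_len(n_sec * rate_hz)], nrow = rate_hz)
  new_rating_trace(colMeans(m), n_levels)
}

#' Flag epochs with extreme voltages
#'
#' An epoch is flagged iff any non-excluded channel strictly exceeds
#' `threshold_uv` in absolute value anywhere in that second. The frontal /
#' EOG-adjacent channels Fp1, Fp2, F7, F8 are excluded by default. The
#' flags feed the subject-exclusion rule only; flagged epochs are not
#' removed from decoding input.
#'
#' @param rec an `eeg_recording`
#' @param threshold_uv voltage threshold in uV (> 0)
#' @param excluded_channels channel labels ignored by the screen
#' @return integer vector of flagged epoch indices (1-based)
#' @export
screen_epochs <- function(rec, threshold_uv = 100,
                          excluded_channels = c("Fp1", "Fp2", "F7", "F8")) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_that(threshold_uv > 0, "threshold must be positive")
  unknown <- setdiff(excluded_channels, rec$channel_labels)
  if (length(unknown))
    stop_invalid("unknown excluded channel label(s): ",
                 paste(unknown, collapse = ", "))
  keep <- !(rec$channel_labels %in% excluded_channels)
  n_epochs <- ncol(rec$data) %/% rec$fs
  x <- abs(rec$data[keep, seq_len(n_epochs * rec$fs), drop = FALSE])
  epoch_of <- rep(seq_len(n_epochs), each = rec$fs)
  peak <- vapply(split(apply(x, 2, max), epoch_of), max, numeric(1))
  unname(which(peak > threshold_uv))
}

#' Subject-exclusion rule from the epoch screen
#'
#' @param n_bad_epochs number of flagged 1-s epochs
#' @param max_bad strict threshold (exclude iff `n_bad_epochs > max_bad`)
#' @return `TRUE` if the subject is to be excluded
#' @export
exclude_subject <- function(n_bad_epochs, max_bad = 90) {
  assert_that(n_bad_epochs >= 0, "negative epoch count")
  n_bad_epochs > max_bad
}

#' Cut a recording (or component matrix) into consecutive 1-s epochs
#'
#' Epoch k covers samples `[(k-1)*fs, k*fs)` and is aligned with rating
#' second k. A trailing remainder shorter than one epoch is dropped with a
#' message.
#'
#' @param rec an `eeg_recording`, or a channels-by-samples matrix
#' @param fs sampling rate (taken from `rec` if it is a recording)
#' @param epoch_length_s epoch length in seconds
#' @return object of class `epoched_data`: `tensor` of dim
#'   epochs x samples-per-epoch x channels, plus `fs`, `epoch_length_s`
#' @export
epoch_data <- function(rec, fs = NULL, epoch_length_s = 1) {
  if (inherits(rec, "eeg_recording")) {
    x <- rec$data; fs <- rec$fs
  } else {
    x <- as.matrix(rec)
    assert_that(!is.null(fs), "fs required for matrix input")
  }
  spe <- round(fs * epoch_length_s)
  n <- ncol(x)
  if (spe > n) stop_invalid("epoch length exceeds recording duration")
  n_epochs <- n %/% spe
  if (n %% spe != 0)
    message("dropping trailing remainder of ", n %% spe, " samples")
  tens <- array(0, dim = c(n_epochs, spe, nrow(x)))
  for (ch in seq_len(nrow(x)))
    tens[, , ch] <- matrix(x[ch, seq_len(n_epochs * spe)],
                           nrow = n_epochs, byrow = TRUE)
  structure(list(tensor = tens, fs = fs, epoch_length_s = epoch_length_s),
            class = "epoched_data")
}

#' Tertile labels from a rating trace
#'
#' Rank-based split into low / mid / high thirds (class sizes differ by at
#' most one; 270 epochs give exactly 90/90/90). Ties are broken by stable
#' rank order (earlier epoch to the lower tertile). The mid class is
#' discarded by the binary decoders.
#'
#' @param trace a `rating_trace` (or numeric vector of per-epoch ratings)
#' @return object of class `label_set`: factor `classes` with levels
#'   low/mid/high and `boundaries` (the two tertile cut ranks)
#' @export
tertile_labels <- function(trace) {
  v <- if (inherits(trace, "rating_trace")) trace$values else as.numeric(trace)
  n <- length(v)
  assert_that(n >= 3, "need at least 3 epochs")
  if (stats::sd(v) == 0)
    stop_degenerate("constant rating trace: no tertile split possible")
  r <- rank(v, ties.method = "first")
  base <- n %/% 3; rem <- n %% 3
  sizes <- base + c(rem >= 1, 0, rem >= 2)   # remainder to low, then high
  cuts <- cumsum(sizes[1:2])
  cls <- cut(r, breaks = c(0, cuts[1], cuts[2], n),
             labels = c("low", "mid", "high"))
  structure(list(classes = cls, boundaries = cuts), class = "label_set")
}

#' Write an epoch label table to CSV (columns: epoch, rating, class)
#' @param trace a `rating_trace`
#' @param labels a `label_set` for the same epochs
#' @param path output file path
#' @export
labels_to_csv <- function(trace, labels, path) {
  utils::write.csv(data.frame(epoch = seq_along(trace$values),
                              rating = trace$values,
                              class = as.character(labels$classes)),
                   path, row.names = FALSE)
  invisible(path)
}
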