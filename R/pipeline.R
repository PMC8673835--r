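# Orchestration: config-driven end-to-end runs over simulated subjects,
# cohort aggregation, and the break-exclusion control.

#' Run configuration for the end-to-end pipeline
#'
#' Bundles the generator configuration with all analysis parameters; every
#' stochastic stage draws its seed deterministically from the subject seed,
#' so a run is reproducible from its config alone.
#'
#' @param synth a [synth_config()] describing the simulated subject
#' @param n_perm permutations for SPoC and block-permutation tests
#' @param k_folds cross-validation folds
#' @param n_subblocks chronological sub-blocks for the blocked CV
#' @param min_components minimum selected SSD components per subject
#' @param selection_threshold criterion-A threshold (log-residual scale)
#' @param flank_sd criterion-B margin in SD units
#' @param run_lstm train the LSTM decoder as well?
#' @param lstm_hp an [hp_config()] for the LSTM branch
#' @param include_break analyse the full experience (TRUE) or drop the
#'   break segment (FALSE)
#' @return object of class `run_config`
#' @export
run_config <- function(synth = synth_config(), n_perm = 200, k_folds = 10,
                       n_subblocks = 3, min_components = 4,
                       selection_threshold = 0.35, flank_sd = 1.45,
                       run_lstm = FALSE, lstm_hp = hp_config(),
                       include_break = TRUE) {
  assert_that(n_perm >= 100, "need at least 100 permutations")
  structure(list(synth = synth, n_perm = n_perm, k_folds = k_folds,
                 n_subblocks = n_subblocks, min_components = min_components,
                 selection_threshold = selection_threshold,
                 flank_sd = flank_sd, run_lstm = run_lstm,
                 lstm_hp = lstm_hp, include_break = include_break),
            class = "run_config")
}

# Core per-subject analysis on an already-cropped recording and its
# per-second rating trace. Decoder failures are caught and reported in the
# summary rather than aborting the run.
analyse_subject <- function(rec, trace, config, subject_id = "s1") {
  seed <- config$synth$seed
  stages <- c("preprocess", "spectral", "ssd")
  summary <- list(subject = subject_id, excluded = FALSE, error = NULL)

  n_bad <- length(screen_epochs(rec))
  summary$n_bad_epochs <- n_bad
  if (exclude_subject(n_bad)) {
    summary$excluded <- TRUE
    summary$exclusion_reason <- "epoch screen"
    return(list(summary = summary, stages = stages[1]))
  }

  peak <- detect_alpha_peak(rec)
  summary$alpha_peak_hz <- peak$alpha_peak_hz
  bands <- ssd_bands(peak$alpha_peak_hz)
  ssd <- ssd_decompose(rec, bands)
  sel <- select_components(ssd, peak$alpha_peak_hz,
                           threshold = config$selection_threshold,
                           flank_sd = config$flank_sd)
  summary$n_selected <- length(sel)
  if (!require_min_components(sel, config$min_components)) {
    summary$excluded <- TRUE
    summary$exclusion_reason <- "fewer selected SSD components than required"
    return(list(summary = summary, stages = stages))
  }

  comp <- ssd$components_signal[sel, , drop = FALSE]
  epochs <- epoch_data(comp, fs = rec$fs)
  cov <- epoch_covariances(epochs)
  labels <- tryCatch(tertile_labels(trace), error = function(e) e)
  if (inherits(labels, "error")) {
    summary$error <- c(summary$error,
                       paste0("labels: ", conditionMessage(labels)))
    labels <- NULL
  }
  stages <- c(stages, "spoc", "csp")

  spoc <- tryCatch(
    spoc_permutation_test(cov, trace$z, n_perm = config$n_perm,
                          seed = derive_seed(seed, 11L)),
    error = function(e) e)
  if (inherits(spoc, "error")) {
    summary$error <- c(summary$error, paste0("spoc: ", conditionMessage(spoc)))
  } else {
    summary$spoc_lambda <- spoc$lambda
    summary$spoc_r <- spoc$r
    summary$spoc_p <- spoc$p_value
    summary$spoc_null_mean <- mean(spoc$null_r)
  }

  csp_out <- if (is.null(labels)) NULL else tryCatch({
    bl <- binary_labels(labels)
    cov_ret <- subset_cov(cov, bl$idx)
    rcv <- randomized_cv(cov_ret, bl$y, k = config$k_folds,
                         seed = derive_seed(seed, 12L))
    scv <- subblocked_cv(cov_ret, bl$y, n_subblocks = config$n_subblocks,
                         k = config$k_folds, seed = derive_seed(seed, 13L))
    bp <- csp_block_permutation(
      cov_ret, bl$y, n_subblocks = config$n_subblocks, k = config$k_folds,
      n_perm = config$n_perm, seed = derive_seed(seed, 14L))
    list(rcv = rcv, scv = scv, bp = bp, bl = bl)
  }, error = function(e) e)
  if (inherits(csp_out, "error")) {
    summary$error <- c(summary$error,
                       paste0("csp: ", conditionMessage(csp_out)))
    csp_out <- NULL
  } else if (!is.null(csp_out)) {
    summary$csp_acc <- csp_out$rcv$mean_accuracy
    summary$csp_p <- exact_binomial_test(
      sum(csp_out$rcv$predictions == csp_out$rcv$truth),
      n_total = length(csp_out$rcv$truth))
    summary$csp_auc <- csp_out$scv$roc_auc
    summary$csp_auc_p <- csp_out$bp$p_value
  }

  lstm_out <- NULL
  if (isTRUE(config$run_lstm) && !is.null(csp_out)) {
    stages <- c(stages, "lstm")
    lstm_out <- tryCatch({
      ds <- build_lstm_dataset(epochs, labels,
                               n_components = config$lstm_hp$n_components)
      lstm_cv(ds, config$lstm_hp, k = config$k_folds,
              folds = csp_out$rcv$folds)
    }, error = function(e) e)
    if (inherits(lstm_out, "error")) {
      summary$error <- c(summary$error,
                         paste0("lstm: ", conditionMessage(lstm_out)))
      lstm_out <- NULL
    } else {
      summary$lstm_acc <- lstm_out$mean_accuracy
      correct <- sum(lstm_out$predictions ==
                       ifelse(csp_out$bl$y == "high", 1, -1))
      summary$lstm_p <- exact_binomial_test(correct,
                                            n_total = length(csp_out$bl$y))
    }
  }
  stages <- c(stages, "evaluate")
  list(summary = summary, stages = stages,
       artifacts = list(ssd = ssd, selected = sel, spoc = spoc,
                        csp = csp_out, lstm = lstm_out, labels = labels))
}

#' Run the full pipeline for one subject
#'
#' Simulates a subject from the configured generator (or takes a supplied
#' recording + trace), then runs preprocessing, alpha-peak detection, SSD
#' with component selection and the minimum-component rule, SPoC with its
#' permutation test, CSP with randomized and sub-blocked cross-validation
#' and a block-permutation null, and optionally the LSTM decoder.
#'
#' @param config a [run_config()]
#' @param subject_id identifier carried into the summary
#' @param recording,trace optional pre-made `eeg_recording` and
#'   `rating_trace`; when omitted, a subject is simulated from
#'   `config$synth`
#' @return list with `summary` (per-model metrics and p-values, exclusion
#'   flags, errors), `manifest` (stages run and key parameters), and the
#'   per-stage `artifacts`
#' @export
run_subject <- function(config = run_config(), subject_id = "s1",
                        recording = NULL, trace = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(recording)) {
    sim <- generate_subject(config$synth)
    recording <- sim$recording
    trace <- sim$trace
    gt <- sim$ground_truth
  } else gt <- NULL
  rec <- crop_experience(recording, include_break = config$include_break)
  if (!config$include_break) {
    keep_sec <- segment_seconds(recording, include_break = FALSE)
    trace <- new_rating_trace(trace$values[keep_sec], trace$n_levels)
  }
  out <- analyse_subject(rec, trace, config, subject_id)
  out$manifest <- list(subject = subject_id, stages = out$stages,
                       n_perm = config$n_perm, k_folds = config$k_folds,
                       include_break = config$include_break,
                       seed = config$synth$seed)
  out$ground_truth <- gt
  out$trace <- trace
  out
}

# Seconds of the experience belonging to the kept segments (used to align
# the rating trace with a break-free crop).
segment_seconds <- function(rec, include_break = TRUE) {
  m <- rec$segment_marks / rec$fs
  segs <- if (include_break) 1:3 else c(1, 3)
  unlist(lapply(segs, function(k) seq(m[k] + 1, m[k + 1])))
}

#' Run a simulated cohort
#'
#' Per-subject seeds are derived deterministically from the cohort seed.
#' Group statistics are computed over non-excluded subjects; group-level
#' errors (e.g. too few subjects for a t-test) are captured in the report
#' rather than thrown.
#'
#' @param config a [run_config()] used as the template for every subject
#' @param n_subjects cohort size (>= 1)
#' @param seed cohort seed
#' @return list with `subjects` (per-subject summaries), `report`
#'   (data.frame from [group_report()]), and `group` (SPoC group test,
#'   CSP/LSTM mean tests, or the error messages they raised)
#' @export
run_cohort <- function(config = run_config(), n_subjects = 10, seed = 1L) {
  assert_that(n_subjects >= 1, "need at least one subject")
  subjects <- lapply(seq_len(n_subjects), function(i) {
    cfg <- config
    cfg$synth$seed <- derive_seed(seed, i)
    run_subject(cfg, subject_id = sprintf("sim%03d", i))
  })
  summaries <- lapply(subjects, `[[`, "summary")
  report <- group_report(summaries)
  ok <- !report$excluded & !is.na(report$SPOC_CORR)
  if (!any(ok)) stop_degenerate("all subjects excluded: empty cohort")
  grab <- function(expr) tryCatch(expr, error = function(e)
    list(error = conditionMessage(e)))
  nulls <- vapply(summaries[ok], function(s)
    s$spoc_null_mean %||% NA_real_, numeric(1))
  group <- list(
    spoc = grab(spoc_group_test(report$SPOC_CORR[ok], nulls)),
    csp_acc = grab(group_mean_test(report$CSP_acc[ok])),
    csp_auc = grab(group_mean_test(report$CSP_auc[ok])),
    lstm_acc = if (any(!is.na(report$LSTM_acc[ok])))
      grab(group_mean_test(report$LSTM_acc[ok][!is.na(report$LSTM_acc[ok])]))
    else NULL)
  list(subjects = summaries, report = report, group = group)
}

#' Break-exclusion control analysis
#'
#' Reruns tertile labelling, SPoC and CSP (sub-blocked CV with a
#' block-permutation null) on the experience without the break segment
#' (240 s under the study defaults); SSD filters are refit on the
#' break-free data. Returns the with-break and without-break summaries
#' side by side as input for paired comparisons.
#'
#' @param config a [run_config()] (its `include_break` is overridden)
#' @param subject_id identifier carried into the summaries
#' @return list with `with_break` and `without_break` subject results and
#'   `paired` (data.frame of the shared metrics)
#' @export
run_break_exclusion_control <- function(config = run_config(),
                                        subject_id = "s1") {
  cfg_with <- config; cfg_with$include_break <- TRUE
  cfg_without <- config; cfg_without$include_break <- FALSE
  with_break <- run_subject(cfg_with, subject_id)
  without_break <- run_subject(cfg_without, subject_id)
  pull <- function(s, f) s$summary[[f]] %||% NA_real_
  paired <- data.frame(
    metric = c("spoc_r", "csp_auc"),
    with_break = c(pull(with_break, "spoc_r"), pull(with_break, "csp_auc")),
    without_break = c(pull(without_break, "spoc_r"),
                      pull(without_break, "csp_auc")))
  list(with_break = with_break, without_break = without_break,
       paired = paired)
}

#' Serialize a subject summary to JSON
#' @param summary a summary list from [run_subject()]
#' @param path output file path
#' @export
summary_to_json <- function(summary, path) {
  jsonlite::write_json(summary[!vapply(summary, is.null, logical(1))],
                       path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}
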