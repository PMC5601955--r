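#' Motion Test configuration
#'
#' The Motion Test prompts each trained movement (in random order) and counts
#' classifier predictions at the analysis-window cadence until a required
#' number of correct predictions accumulates or a timeout expires. The first
#' prediction becomes available one full window plus the processing latency
#' after the prompt (200 + 11 = 211 ms under the defaults), and one new
#' prediction follows every window increment (50 ms). The default latency of
#' 11 ms makes the two standard floors hold exactly: 0.211 s minimum
#' selection time and 0.211 + 19 x 0.05 = 1.161 ~ 1.16 s minimum completion
#' time for 20 required correct predictions.
#'
#' @param required_correct correct predictions needed to complete a motion
#' @param timeout_s trial timeout in seconds, clocked from the prompt
#' @param window_ms,increment_ms analysis-window cadence
#' @param processing_latency_ms latency between window end and prediction
#' @param trials_per_motion prompts per motion within one test
#' @param n_tests number of test repetitions (the protocol runs the test
#'   twice)
#' @param include_rest_prompts whether rest is among the prompted motions
#'   (default `FALSE`: results are reported for the 8 movements)
#' @return object of class `motion_test_config`
#' @export
motion_test_config <- function(required_correct = 20, timeout_s = 10,
                               window_ms = 200, increment_ms = 50,
                               processing_latency_ms = 11,
                               trials_per_motion = 1, n_tests = 2,
                               include_rest_prompts = FALSE) {
  check_scalar_num(required_correct, "required_correct", lower = 1, integer = TRUE)
  check_scalar_num(timeout_s, "timeout_s", lower = 0, strict_lower = TRUE)
  check_scalar_num(window_ms, "window_ms", lower = 0, strict_lower = TRUE)
  check_scalar_num(increment_ms, "increment_ms", lower = 0, strict_lower = TRUE)
  if (increment_ms > window_ms)
    stop_invalid("increment_ms", "must be <= window_ms")
  check_scalar_num(processing_latency_ms, "processing_latency_ms", lower = 0)
  check_scalar_num(trials_per_motion, "trials_per_motion", lower = 1, integer = TRUE)
  check_scalar_num(n_tests, "n_tests", lower = 1, integer = TRUE)
  floor_s <- (window_ms + (required_correct - 1) * increment_ms) / 1000
  if (timeout_s <= floor_s)
    stop_invalid("timeout_s",
                 sprintf("must exceed the theoretical completion floor %.3f s", floor_s))
  structure(list(required_correct = as.integer(required_correct),
                 timeout_s = timeout_s, window_ms = window_ms,
                 increment_ms = increment_ms,
                 processing_latency_ms = processing_latency_ms,
                 trials_per_motion = as.integer(trials_per_motion),
                 n_tests = as.integer(n_tests),
                 include_rest_prompts = isTRUE(include_rest_prompts)),
            class = "motion_test_config")
}

# Time of the k-th prediction after the prompt, in seconds.
event_times <- function(k, config) {
  (config$window_ms + config$processing_latency_ms) / 1000 +
    (k - 1) * config$increment_ms / 1000
}

#' Build a scripted prediction stream
#'
#' Wraps an ordered vector of predicted labels into the event timeline the
#' Motion Test uses: the k-th prediction occurs at
#' `(window_ms + processing_latency_ms)/1000 + (k-1) * increment_ms/1000`
#' seconds after the prompt. Scripted streams drive the metric functions in
#' tests and worked examples without a classifier.
#'
#' @param predictions character vector of predicted class labels, in order
#' @param prompted the prompted class label
#' @param config a [motion_test_config()]
#' @return a `prediction_stream`: data.frame `time_s`, `pred` with the
#'   prompt and config attached as attributes
#' @export
scripted_stream <- function(predictions, prompted,
                            config = motion_test_config()) {
  k <- seq_along(predictions)
  structure(data.frame(time_s = event_times(k, config),
                       pred = as.character(predictions)),
            prompted = prompted, config = config,
            class = c("prediction_stream", "data.frame"))
}

#' Evaluate one Motion Test trial from a prediction stream
#'
#' Applies the four real-time metric definitions to the stream of (time,
#' prediction) events of one prompted motion:
#' * selection time — elapsed time from the first non-rest prediction to the
#'   first correct prediction, plus the first-window latency
#'   (`window_ms + processing_latency_ms`), so an immediately correct first
#'   prediction scores the 211 ms floor;
#' * completion time — same origin, to the prediction that reaches
#'   `required_correct` correct predictions (floor 1.16 s under defaults);
#' * completed — whether that happens before the timeout (clocked from the
#'   prompt);
#' * real-time accuracy — `required_correct` divided by the number of
#'   predictions from the first non-rest prediction through the completing
#'   one (only defined for completed trials). Correct predictions need not
#'   be consecutive.
#'
#' @param stream a `prediction_stream` (e.g. from [scripted_stream()])
#' @param prompted prompted class; defaults to the stream's attribute
#' @param config a [motion_test_config()]; defaults to the stream's
#' @param rest_label label of the rest class
#' @return a `motion_trial`: list with `prompted`, `completed`,
#'   `selection_time_s`, `completion_time_s`, `realtime_accuracy`,
#'   `n_predictions` (to completion, from the first non-rest), and
#'   `n_events` seen before timeout. Undefined quantities are `NA`.
#' @export
evaluate_trial <- function(stream, prompted = attr(stream, "prompted"),
                           config = attr(stream, "config"),
                           rest_label = "rest") {
  if (nrow(stream) == 0) stop_invalid("stream", "must contain at least one event")
  keep <- stream$time_s <= config$timeout_s
  ev <- stream[keep, , drop = FALSE]
  latency_s <- (config$window_ms + config$processing_latency_ms) / 1000
  res <- list(prompted = prompted, completed = FALSE,
              selection_time_s = NA_real_, completion_time_s = NA_real_,
              realtime_accuracy = NA_real_, n_predictions = NA_integer_,
              n_events = nrow(ev))
  j0 <- which(ev$pred != rest_label)[1]
  if (is.na(j0)) return(structure(res, class = "motion_trial"))
  correct <- which(ev$pred == prompted & seq_len(nrow(ev)) >= j0)
  if (length(correct) >= 1) {
    res$selection_time_s <- ev$time_s[correct[1]] - ev$time_s[j0] + latency_s
  }
  rc <- config$required_correct
  if (length(correct) >= rc) {
    jc <- correct[rc]
    res$completed <- TRUE
    res$completion_time_s <- ev$time_s[jc] - ev$time_s[j0] + latency_s
    res$n_predictions <- jc - j0 + 1L
    res$realtime_accuracy <- rc / res$n_predictions
  }
  structure(res, class = "motion_trial")
}

#' Selection time of a prediction stream
#'
#' Convenience wrapper over [evaluate_trial()]; returns `NA` when no non-rest
#' or no correct prediction occurs before the timeout (undefined is a value,
#' not an error).
#'
#' @inheritParams evaluate_trial
#' @return seconds, or `NA`
#' @export
selection_time <- function(stream, prompted = attr(stream, "prompted"),
                           config = attr(stream, "config"),
                           rest_label = "rest") {
  evaluate_trial(stream, prompted, config, rest_label)$selection_time_s
}

#' Real-time accuracy of a completed trial
#'
#' `required_correct / k`, where `k` counts predictions from the first
#' non-rest prediction through the completing one; a trial completing on its
#' 25th prediction scores 20/25 = 80%.
#'
#' @inheritParams evaluate_trial
#' @return fraction in (0, 1]; errors if the trial did not complete
#' @export
realtime_accuracy <- function(stream, prompted = attr(stream, "prompted"),
                              config = attr(stream, "config"),
                              rest_label = "rest") {
  tr <- evaluate_trial(stream, prompted, config, rest_label)
  if (!tr$completed)
    stop("realtime_accuracy is only defined for completed trials", call. = FALSE)
  tr$realtime_accuracy
}

#' Run the Motion Test against a trained classifier
#'
#' Simulates the real-time evaluation protocol: for each test repetition the
#' trained movements are prompted in seeded random order; for each prompt a
#' fresh synthetic signal of that movement is streamed (trapezoidal onset
#' ramp, then sustained contraction), windowed at the configured cadence,
#' featurized, and classified, and the resulting prediction stream is scored
#' with [evaluate_trial()]. Deterministic for a fixed seed.
#'
#' @param clf an `ovo_classifier`
#' @param protocol,model,frontend the generator context (must match the
#'   classifier's channel/feature contract)
#' @param config a [motion_test_config()]
#' @param fspec the [feature_spec()] used at training time
#' @param seed RNG seed for prompt order and signal synthesis
#' @param rest_label rest-class label
#' @return a `motion_test_result`: list with `trials` (one row per prompt),
#'   `aggregates`, and `config`
#' @export
run_motion_test <- function(clf, protocol, model, frontend = frontend_spec(),
                            config = motion_test_config(),
                            fspec = feature_spec(), seed = 1,
                            rest_label = "rest") {
  n_feat_expected <- protocol$n_channels * length(fspec$features)
  if (n_feat_expected != length(clf$feature_names))
    stop_invalid("clf", sprintf("expects %d features; generator context provides %d",
                                length(clf$feature_names), n_feat_expected))
  motions <- protocol$movements
  if (config$include_rest_prompts) motions <- c(motions, rest_label)
  trials <- list()
  t_i <- 0L
  for (test_i in seq_len(config$n_tests)) {
    order_seed <- derive_seed(seed, 1000L + test_i)
    prompts <- with_seed(order_seed, sample(rep(motions, config$trials_per_motion)))
    for (p_i in seq_along(prompts)) {
      t_i <- t_i + 1L
      stream_seed <- derive_seed(seed, 2000L + 100L * test_i + p_i)
      stream <- classify_stream(clf, prompts[p_i], protocol, model, frontend,
                                config, fspec, stream_seed, rest_label)
      tr <- evaluate_trial(stream, prompts[p_i], config, rest_label)
      trials[[t_i]] <- data.frame(test = test_i, prompted = prompts[p_i],
                                  completed = tr$completed,
                                  selection_time_s = tr$selection_time_s,
                                  completion_time_s = tr$completion_time_s,
                                  realtime_accuracy = tr$realtime_accuracy,
                                  n_predictions = tr$n_predictions)
    }
  }
  trials <- do.call(rbind, trials)
  structure(list(trials = trials, aggregates = aggregate_trials(trials),
                 config = config),
            class = "motion_test_result")
}

# Stream one prompted motion through the classifier at the window cadence.
classify_stream <- function(clf, prompted, protocol, model, frontend, config,
                            fspec, seed, rest_label) {
  fs <- protocol$sampling_rate
  n_total <- ceiling(config$timeout_s * fs)
  w <- floor(config$window_ms * fs / 1000)
  inc <- floor(config$increment_ms * fs / 1000)
  is_rest <- identical(prompted, rest_label)
  m <- if (is_rest) NA_integer_ else match(prompted, protocol$movements)
  sig <- with_seed(seed, {
    carrier <- emg_carrier(n_total, protocol$n_channels, fs)
    noise <- matrix(stats::rnorm(n_total * protocol$n_channels,
                                 sd = model$baseline_noise_rms),
                    n_total, protocol$n_channels)
    if (is_rest) {
      raw <- noise
    } else {
      n_ramp <- floor(model$ramp_fraction * protocol$contraction_s * fs)
      env <- rep(1, n_total)
      if (n_ramp > 0) env[seq_len(n_ramp)] <- seq_len(n_ramp) / n_ramp
      amp <- model$activation[m, ] * model$mvc_fraction * model$mvc_rms
      raw <- carrier * matrix(amp, n_total, protocol$n_channels, byrow = TRUE) * env +
        noise
    }
    hp <- butter_design(frontend$hp_order, frontend$hp_cutoff_hz, fs, "high")
    lp <- butter_design(frontend$lp_order, frontend$lp_cutoff_hz, fs, "low")
    quantize_midtread(iir_filter(lp$b, lp$a, iir_filter(hp$b, hp$a, noise_mix(raw))) *
                        frontend$gain,
                      frontend$bits, frontend$fullscale_v)
  })
  n_events <- floor((n_total - w) / inc) + 1
  # only events whose prediction time falls within the timeout matter
  n_events <- min(n_events,
                  floor((config$timeout_s * 1000 - config$window_ms -
                           config$processing_latency_ms) /
                          config$increment_ms) + 1)
  starts <- (seq_len(n_events) - 1L) * inc
  ws <- structure(list(windows = data.frame(label = prompted, start = starts,
                                            end = starts + w),
                       signals = stats::setNames(list(sig), prompted),
                       window_samples = w, fs = fs),
                  class = "window_set")
  fm <- extract_features(ws, fspec)
  preds <- predict(clf, fm$x)
  scripted_stream(preds, prompted, config)
}

noise_mix <- function(x) x # placeholder hook for crosstalk experiments

aggregate_trials <- function(trials) {
  comp <- trials[trials$completed, , drop = FALSE]
  mean_se <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(c(mean = NA_real_, se = NA_real_))
    c(mean = mean(v),
      se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }
  list(n_trials = nrow(trials),
       n_completed = nrow(comp),
       completion_pct = 100 * nrow(comp) / nrow(trials),
       selection_time_s = mean_se(comp$selection_time_s),
       completion_time_s = mean_se(comp$completion_time_s),
       realtime_accuracy = mean_se(comp$realtime_accuracy))
}

#' @export
print.motion_test_result <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("<motion_test_result> %d trials, %.1f%% completed\n",
              a$n_trials, a$completion_pct))
  cat(sprintf("  selection time  %.3f s (SE %.3f)\n",
              a$selection_time_s["mean"], a$selection_time_s["se"]))
  cat(sprintf("  completion time %.3f s (SE %.3f)\n",
              a$completion_time_s["mean"], a$completion_time_s["se"]))
  cat(sprintf("  real-time acc   %.1f%% (SE %.1f)\n",
              100 * a$realtime_accuracy["mean"], 100 * a$realtime_accuracy["se"]))
  invisible(x)
}

#' Cumulative completion curve
#'
#' The fraction of attempted motions completed as a function of elapsed
#' time: a non-decreasing right-continuous step function rising from 0 at
#' `t = 0` to the completion percentage at the timeout. Equals the empirical
#' CDF of the completion times scaled by the completed fraction.
#'
#' @param result a `motion_test_result`, or a data.frame of trials with
#'   `completed` and `completion_time_s` columns
#' @return data.frame with `time_s` (step locations, starting at 0) and
#'   `completion_pct` (value from that time on)
#' @export
cumulative_completion_curve <- function(result) {
  trials <- if (inherits(result, "motion_test_result")) result$trials else result
  if (nrow(trials) == 0) stop_invalid("result", "needs at least one trial")
  times <- sort(trials$completion_time_s[trials$completed])
  steps <- unique(times)
  pct <- vapply(steps, function(t) 100 * sum(times <= t) / nrow(trials),
                numeric(1))
  data.frame(time_s = c(0, steps), completion_pct = c(0, pct))
}

#' Write a Motion Test report (CSV trials + JSON summary)
#'
#' @param result a `motion_test_result`
#' @param dir output directory (created if needed)
#' @return `dir` invisibly
#' @export
write_motion_test_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(aggregates = result$aggregates,
         curve = cumulative_completion_curve(result),
         config = unclass(result$config)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
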