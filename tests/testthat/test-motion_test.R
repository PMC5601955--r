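# motion_test: metric definitions on scripted streams, floors, the live loop.

cfg <- motion_test_config() # 20 correct, 10 s, 200/50 ms, 11 ms latency

test_that("an always-correct stream hits both floors exactly", {
  st <- scripted_stream(rep("knee_flexion", 30), "knee_flexion", cfg)
  tr <- evaluate_trial(st)
  expect_true(tr$completed)
  expect_equal(tr$selection_time_s, 0.211)
  expect_equal(tr$completion_time_s, 1.161)
  expect_equal(round(tr$completion_time_s, 2), 1.16)
  expect_equal(tr$realtime_accuracy, 1)
  expect_equal(tr$n_predictions, 20L)
})

test_that("the 25-window worked example yields 80% real-time accuracy", {
  # first prediction non-rest (wrong), 20 of the first 25 correct,
  # the 25th being the 20th correct
  preds <- c(rep("wrong", 5), rep("target", 20))
  st <- scripted_stream(preds, "target", cfg)
  tr <- evaluate_trial(st)
  expect_true(tr$completed)
  expect_equal(tr$n_predictions, 25L)
  expect_equal(tr$realtime_accuracy, 0.80)
  expect_equal(realtime_accuracy(st), 0.80)
  # 20 correct, the 20th on the 40th prediction from the first non-rest -> 50%
  preds40 <- rep(c("wrong", "target"), 20)
  expect_equal(realtime_accuracy(scripted_stream(preds40, "target", cfg)), 0.5)
  # correct predictions need not be consecutive
  expect_true(evaluate_trial(scripted_stream(preds40, "target", cfg))$completed)
})

test_that("selection time follows the documented event arithmetic", {
  # first non-rest at 211 ms is correct -> the 211 ms floor
  expect_equal(selection_time(scripted_stream(rep("t", 25), "t", cfg)), 0.211)
  # first non-rest (wrong) at 211 ms, first correct at 411 ms -> 0.200 + floor
  preds <- c("w", rep("w", 3), rep("t", 20))
  expect_equal(selection_time(scripted_stream(preds, "t", cfg)),
               0.200 + 0.211)
  # rest predictions before the first non-rest do not change the metrics
  with_rest <- scripted_stream(c(rep("rest", 6), rep("t", 20)), "t", cfg)
  tr <- evaluate_trial(with_rest)
  expect_equal(tr$selection_time_s, 0.211)
  expect_equal(tr$completion_time_s, 1.161)
  # all-rest stream: undefined selection, not completed
  all_rest <- scripted_stream(rep("rest", 50), "t", cfg)
  expect_true(is.na(selection_time(all_rest)))
  expect_false(evaluate_trial(all_rest)$completed)
  # never-correct stream: not completed, excluded from accuracy
  never <- scripted_stream(rep("w", 50), "t", cfg)
  expect_false(evaluate_trial(never)$completed)
  expect_error(realtime_accuracy(never), "completed")
})

test_that("the timeout truncates streams (clock starts at the prompt)", {
  # 20th correct would arrive after 10 s: predictions beyond timeout ignored
  n_within <- floor((10 - 0.211) / 0.05) + 1 # events at/before 10 s
  preds <- c(rep("rest", n_within - 5), rep("t", 25))
  tr <- evaluate_trial(scripted_stream(preds, "t", cfg))
  expect_false(tr$completed)
  expect_equal(tr$n_events, n_within)
  # config invariant: timeout must exceed the completion floor
  expect_error(motion_test_config(timeout_s = 1.0), "floor")
})

test_that("floors hold across randomized scripted streams (property)", {
  set.seed(17)
  for (i in 1:200) {
    preds <- sample(c("rest", "a", "b"), 60, replace = TRUE,
                    prob = c(0.2, 0.5, 0.3))
    tr <- evaluate_trial(scripted_stream(preds, "a", cfg))
    if (!is.na(tr$selection_time_s)) expect_gte(tr$selection_time_s, 0.211)
    if (tr$completed) {
      expect_gte(tr$completion_time_s, 1.161 - 1e-12)
      expect_gte(tr$completion_time_s, tr$selection_time_s)
      expect_true(tr$realtime_accuracy > 0 && tr$realtime_accuracy <= 1)
      expect_equal(tr$realtime_accuracy, 20 / tr$n_predictions)
      # completion = selection + (k - 1 - j) * increment; j = first-correct
      # offset among post-selection events (independent replay)
      ev <- preds[seq_len(tr$n_events)]
      j0 <- which(ev != "rest")[1]
      j <- which(ev == "a" & seq_along(ev) >= j0)[1] - j0
      expect_equal(tr$completion_time_s,
                   tr$selection_time_s + (tr$n_predictions - 1 - j) * 0.05,
                   tolerance = 1e-12)
    }
  }
})

test_that("cumulative completion curve equals the scaled empirical CDF", {
  trials <- data.frame(
    completed = c(TRUE, TRUE, TRUE, FALSE),
    completion_time_s = c(2, 1.5, 2, NA))
  curve <- cumulative_completion_curve(trials)
  expect_equal(curve$time_s, c(0, 1.5, 2))
  expect_equal(curve$completion_pct, c(0, 25, 75))
  expect_true(all(diff(curve$completion_pct) >= 0))
  # all complete at exactly 1.161 s -> single step to 100
  tr2 <- data.frame(completed = TRUE, completion_time_s = rep(1.161, 8))
  expect_equal(cumulative_completion_curve(tr2)$completion_pct, c(0, 100))
  # no completions -> constant 0
  tr3 <- data.frame(completed = FALSE, completion_time_s = NA_real_)
  expect_equal(cumulative_completion_curve(tr3)$completion_pct, 0)
})

test_that("run_motion_test completes every motion on separable data", {
  p <- small_protocol()
  m <- make_activation_matrix(4, 4, overlap = 0, seed = 21)
  s <- generate_session(p, m, seed = 121)
  fm <- extract_features(windows_from_session(s))
  sp <- split_sets(fm, seed = 1)
  clf <- fit_ovo(fm, sp)
  cfg2 <- motion_test_config(timeout_s = 5)
  mt <- run_motion_test(clf, p, m, config = cfg2, seed = 9)
  expect_equal(nrow(mt$trials), 4 * 2) # 4 motions x 2 tests
  expect_equal(mt$aggregates$completion_pct, 100)
  expect_true(all(mt$trials$selection_time_s >= 0.211))
  expect_true(all(mt$trials$completion_time_s >= 1.161))
  # deterministic per seed
  mt2 <- run_motion_test(clf, p, m, config = cfg2, seed = 9)
  expect_identical(mt$trials, mt2$trials)
  # prompt order varies across tests/seeds but covers every motion per test
  for (t_i in 1:2)
    expect_setequal(mt$trials$prompted[mt$trials$test == t_i], p$movements)
  # report writer produces the CSV + JSON pair
  d <- withr::local_tempdir()
  write_motion_test_report(mt, d)
  expect_true(file.exists(file.path(d, "trials.csv")))
  expect_true(file.exists(file.path(d, "summary.json")))
  # contract mismatch is caught
  expect_error(run_motion_test(clf, protocol_spec(), m, config = cfg2),
               "features")
})
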