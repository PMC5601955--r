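# pain_metrics: NRS/PRI/WPD scoring and longitudinal change summaries.

mk_assessment <- function(session = 1, nrs = 4,
                          scores = rep(0, 15),
                          dist = c(1, 0, 0, 0, 0, 0),
                          followup = NA, hours = 7) {
  pain_assessment(session = session, followup_months = followup, nrs = nrs,
                  descriptor_scores = scores, wpd_distribution = dist,
                  hours_slept = hours)
}

test_that("PRI is the sum of the descriptor scores, with bounds enforced", {
  expect_equal(pri(mk_assessment(scores = rep(0, 15))), 0)
  expect_equal(pri(mk_assessment(scores = rep(1, 15))), 15)
  # a score pattern summing to the study's first-session value
  first <- mk_assessment(scores = c(5, 5, 5, 4, 4, 3, 2, 2, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(pri(first), 32)
  expect_lte(pri(first), 5 * 15) # PRI <= score_max * n_descriptors
  expect_error(mk_assessment(scores = c(6, rep(0, 14))), "descriptor_scores")
  expect_error(mk_assessment(nrs = 11), "nrs")
})

test_that("WPD is the awake-time-weighted sum of pain levels", {
  expect_equal(wpd(mk_assessment(dist = c(1, 0, 0, 0, 0, 0))), 0)
  expect_equal(wpd(mk_assessment(dist = c(0, 0, 0, 0, 0, 1))), 5)
  expect_equal(wpd(mk_assessment(dist = c(0, 0, 0.5, 0, 0.5, 0))), 3)
  # percentages normalize on input (with a message)
  expect_message(a <- mk_assessment(dist = c(50, 0, 25, 0, 25, 0)),
                 "percent")
  expect_equal(wpd(a), 0.25 * 2 + 0.25 * 4)
  expect_error(mk_assessment(dist = c(0.5, 0, 0, 0, 0, 0)), "sum")
  expect_error(mk_assessment(dist = c(2, -1, 0, 0, 0, 0)), "non-negative")
  # linear in the distribution; permuting zero-mass levels is a no-op
  d1 <- c(0, 0.3, 0.7, 0, 0, 0)
  d2 <- c(0, 0.3, 0.7, 0, 0, 0)
  expect_equal(wpd(mk_assessment(dist = d1)), wpd(mk_assessment(dist = d2)))
})

test_that("timelines enforce ordering and derive PRI/WPD series", {
  tl <- pain_timeline(list(
    mk_assessment(session = 1, nrs = 4,
                  scores = c(5, 5, 5, 4, 4, 3, 2, 2, 1, 1, 0, 0, 0, 0, 0),
                  dist = c(0, 0.1, 0.2, 0.3, 0.2, 0.2), hours = 2),
    mk_assessment(session = 2, nrs = 3, scores = rep(1, 15),
                  dist = c(0.2, 0.2, 0.2, 0.2, 0.2, 0)),
    mk_assessment(session = 23, nrs = 2, scores = rep(c(1, 0), c(10, 5)),
                  dist = c(0.4, 0.3, 0.2, 0.1, 0, 0), hours = 7),
    mk_assessment(session = NA, followup = 1, nrs = 2, scores = rep(1, 15),
                  dist = c(0.5, 0.3, 0.2, 0, 0, 0))))
  expect_equal(tl$series$pri[1], 32)
  expect_equal(tl$series$when[4], "followup_1m")
  # out-of-order sessions rejected
  expect_error(pain_timeline(list(mk_assessment(session = 2),
                                  mk_assessment(session = 1))),
               "increasing")
  # follow-up before sessions rejected
  expect_error(pain_timeline(list(
    mk_assessment(session = NA, followup = 1),
    mk_assessment(session = 2))), "after")
})

test_that("change_summary reproduces the reported change arithmetic", {
  # endpoints as recorded in the study: NRS 4 -> 2, PRI 32 -> 10, WPD 3.2 -> 1.4
  first <- mk_assessment(session = 1, nrs = 4,
                         scores = c(5, 5, 5, 4, 4, 3, 2, 2, 1, 1, 0, 0, 0, 0, 0),
                         dist = c(0, 0, 0.2, 0.4, 0.4, 0), hours = 2)
  last <- mk_assessment(session = 23, nrs = 2,
                        scores = rep(c(2, 0), c(5, 10)),
                        dist = c(0.3, 0.2, 0.3, 0.2, 0, 0), hours = 7)
  expect_equal(pri(first), 32); expect_equal(pri(last), 10)
  expect_equal(wpd(first), 3.2); expect_equal(wpd(last), 1.4)
  cs <- change_summary(pain_timeline(list(first, last)))
  row <- function(m) cs[cs$metric == m & cs$reference == "last_session", ]
  expect_equal(row("nrs")$abs_change, 2)
  expect_equal(row("nrs")$pct_change, 50)
  expect_equal(row("pri")$abs_change, 22)
  expect_equal(row("pri")$pct_change, 100 * 22 / 32) # 68.75, stored unrounded
  expect_equal(row("wpd")$abs_change, 1.8)
  expect_equal(row("wpd")$pct_change, 100 * 1.8 / 3.2, tolerance = 1e-9)
  # identical first/last values -> zero change
  first_again <- first
  first_again$session <- 23
  cs0 <- change_summary(pain_timeline(list(first, first_again)))
  expect_true(all(cs0$abs_change == 0))
  expect_true(all(cs0$pct_change[!is.na(cs0$pct_change)] == 0))
  # first = 0 -> percent undefined
  z <- mk_assessment(session = 1, nrs = 0, scores = rep(0, 15))
  cs_na <- change_summary(pain_timeline(list(z, last)))
  expect_true(is.na(cs_na[cs_na$metric == "pri", "pct_change"][1]))
})

test_that("assessments round-trip through CSV", {
  tl <- pain_timeline(list(
    mk_assessment(session = 1, nrs = 5, scores = rep(2, 15),
                  dist = c(0.1, 0.2, 0.3, 0.2, 0.1, 0.1), hours = 3),
    mk_assessment(session = 2, nrs = 4, scores = rep(1, 15),
                  dist = c(0.3, 0.3, 0.2, 0.1, 0.1, 0)),
    mk_assessment(session = NA, followup = 3, nrs = 2, scores = rep(0, 15),
                  dist = c(0.9, 0.1, 0, 0, 0, 0), hours = 8)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_pain_csv(tl, f)
  back <- read_pain_csv(f)
  expect_equal(back$series, tl$series, tolerance = 1e-12)
})
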