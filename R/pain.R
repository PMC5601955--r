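#' A single pain assessment
#'
#' One per-session questionnaire outcome: momentary pain intensity on the
#' numeric rating scale (NRS, 0-10), per-descriptor SF-MPQ scores (default 15
#' descriptors, each scored 0-5), the awake-time distribution over the
#' 6-point pain scale used by the weighted pain distribution (WPD), and hours
#' slept. The distribution may be given as proportions or percentages;
#' percentages are normalized on input with a message.
#'
#' @param session session index (1-based) for treatment sessions, or `NA`
#'   for follow-ups
#' @param followup_months follow-up tag in months (e.g. 1, 3, 6), or `NA`
#'   for treatment sessions
#' @param nrs integer 0-10
#' @param descriptor_scores numeric vector, each score in `[0, score_max]`
#' @param wpd_distribution length-6 non-negative vector `p0..p5`, summing to
#'   1 (tolerance 1e-9) or to 100 (percentages)
#' @param hours_slept hours in [0, 24], or `NA`
#' @param score_max maximum descriptor score (default 5)
#' @param notes free-text phantom length/location notes
#' @return object of class `pain_assessment`
#' @export
pain_assessment <- function(session = NA, followup_months = NA, nrs,
                            descriptor_scores, wpd_distribution,
                            hours_slept = NA, score_max = 5, notes = "") {
  check_scalar_num(nrs, "nrs", lower = 0, upper = 10, integer = TRUE)
  if (!is.numeric(descriptor_scores) || length(descriptor_scores) == 0)
    stop_invalid("descriptor_scores", "must be a non-empty numeric vector")
  if (any(descriptor_scores < 0 | descriptor_scores > score_max))
    stop_invalid("descriptor_scores", sprintf("each score must lie in [0, %g]", score_max))
  if (!is.numeric(wpd_distribution) || length(wpd_distribution) != 6)
    stop_invalid("wpd_distribution", "must have six elements (pain levels 0-5)")
  if (any(wpd_distribution < 0))
    stop_invalid("wpd_distribution", "proportions must be non-negative")
  s <- sum(wpd_distribution)
  if (abs(s - 100) < 1e-6) {
    message("wpd_distribution given as percentages; normalizing to proportions")
    wpd_distribution <- wpd_distribution / 100
  } else if (abs(s - 1) > 1e-9) {
    stop_invalid("wpd_distribution", sprintf("must sum to 1 (or 100), got %g", s))
  }
  if (!is.na(hours_slept))
    check_scalar_num(hours_slept, "hours_slept", lower = 0, upper = 24)
  structure(list(session = session, followup_months = followup_months,
                 nrs = as.integer(nrs), descriptor_scores = descriptor_scores,
                 wpd_distribution = wpd_distribution,
                 hours_slept = hours_slept, score_max = score_max,
                 notes = notes),
            class = "pain_assessment")
}

#' Pain Rating Index
#'
#' The PRI of an assessment: the arithmetic sum of the individual scores
#' given to the pain descriptors.
#'
#' @param assessment a [pain_assessment()]
#' @return non-negative number (integer for integer scores); bounded by
#'   `score_max * n_descriptors`
#' @export
pri <- function(assessment) {
  sum(assessment$descriptor_scores)
}

#' Weighted pain distribution
#'
#' The WPD of an assessment: the weighted sum of pain levels 0-5, each
#' weighted by the proportion of awake time spent at that level —
#' `sum(k * p_k)`, a scalar in [0, 5].
#'
#' @param assessment a [pain_assessment()]
#' @return scalar in [0, 5]
#' @export
wpd <- function(assessment) {
  sum((0:5) * assessment$wpd_distribution)
}

#' Ordered timeline of pain assessments
#'
#' Treatment sessions must come first in strictly increasing session order,
#' followed by follow-ups in increasing months. Derived PRI and WPD series
#' are attached.
#'
#' @param assessments list of [pain_assessment()] objects
#' @return a `pain_timeline`: list with `assessments` and a `series`
#'   data.frame (`when`, `session`, `followup_months`, `nrs`, `pri`, `wpd`,
#'   `hours_slept`)
#' @export
pain_timeline <- function(assessments) {
  if (!length(assessments)) stop_invalid("assessments", "must be non-empty")
  is_fu <- vapply(assessments, function(a) !is.na(a$followup_months), logical(1))
  sess <- vapply(assessments, function(a) as.numeric(a$session), numeric(1))
  fu <- vapply(assessments, function(a) as.numeric(a$followup_months), numeric(1))
  if (any(which(is_fu) < max(c(0, which(!is_fu)))))
    stop_invalid("assessments", "follow-ups must come after all treatment sessions")
  ds <- diff(sess[!is_fu])
  if (length(ds) && any(ds <= 0))
    stop_invalid("assessments", "session order must be strictly increasing")
  if (sum(is_fu) > 1 && any(diff(fu[is_fu]) <= 0))
    stop_invalid("assessments", "follow-ups must be in increasing months")
  series <- data.frame(
    when = ifelse(is_fu, paste0("followup_", fu, "m"),
                  paste0("session_", sess)),
    session = sess,
    followup_months = fu,
    nrs = vapply(assessments, function(a) as.numeric(a$nrs), numeric(1)),
    pri = vapply(assessments, pri, numeric(1)),
    wpd = vapply(assessments, wpd, numeric(1)),
    hours_slept = vapply(assessments, function(a) as.numeric(a$hours_slept),
                         numeric(1)))
  structure(list(assessments = assessments, series = series),
            class = "pain_timeline")
}

#' @export
print.pain_timeline <- function(x, ...) {
  n_fu <- sum(!is.na(x$series$followup_months))
  cat(sprintf("<pain_timeline> %d treatment sessions + %d follow-ups\n",
              nrow(x$series) - n_fu, n_fu))
  invisible(x)
}

#' Longitudinal change summary
#'
#' Absolute and percent change of each outcome metric between the first
#' treatment session and (a) the last treatment session and (b) each
#' follow-up. Absolute change is `first - last` (positive = improvement for
#' pain metrics); percent change is `100 * (first - last) / first` when the
#' first value is positive, otherwise `NA`. Values are stored unrounded; a
#' rounded-to-integer presentation column is included for display.
#'
#' @param timeline a [pain_timeline()]
#' @param metrics metric columns to summarize
#' @return data.frame with `metric`, `reference`, `first`, `value`,
#'   `abs_change`, `pct_change`, `pct_change_rounded`
#' @export
change_summary <- function(timeline,
                           metrics = c("nrs", "pri", "wpd", "hours_slept")) {
  s <- timeline$series
  if (nrow(s) < 2) stop_invalid("timeline", "needs at least two assessments")
  sess_rows <- which(is.na(s$followup_months))
  fu_rows <- which(!is.na(s$followup_months))
  first <- s[sess_rows[1], ]
  refs <- c(stats::setNames(list(s[sess_rows[length(sess_rows)], ]), "last_session"),
            stats::setNames(lapply(fu_rows, function(i) s[i, ]),
                            s$when[fu_rows]))
  out <- list()
  for (mt in metrics) {
    for (rn in names(refs)) {
      f <- first[[mt]]; v <- refs[[rn]][[mt]]
      ac <- f - v
      pc <- if (!is.na(f) && f > 0) 100 * ac / f else NA_real_
      out[[length(out) + 1]] <- data.frame(
        metric = mt, reference = rn, first = f, value = v,
        abs_change = ac, pct_change = pc,
        pct_change_rounded = round(pc))
    }
  }
  do.call(rbind, out)
}

#' Write / read pain assessments as CSV
#'
#' One row per assessment: `session`, `followup_months`, `nrs`, one column
#' per descriptor (`desc01..`), six distribution columns (`p0..p5`), and
#' `hours_slept`.
#'
#' @param timeline a `pain_timeline`
#' @param path CSV file path
#' @return `path` invisibly / a `pain_timeline`
#' @export
write_pain_csv <- function(timeline, path) {
  rows <- lapply(timeline$assessments, function(a) {
    desc <- stats::setNames(as.list(a$descriptor_scores),
                            sprintf("desc%02d", seq_along(a$descriptor_scores)))
    dist <- stats::setNames(as.list(a$wpd_distribution), paste0("p", 0:5))
    as.data.frame(c(list(session = a$session,
                         followup_months = a$followup_months, nrs = a$nrs),
                    desc, dist, list(hours_slept = a$hours_slept)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pain_csv
#' @export
read_pain_csv <- function(path) {
  df <- utils::read.csv(path)
  desc_cols <- grep("^desc", names(df), value = TRUE)
  dist_cols <- paste0("p", 0:5)
  assessments <- lapply(seq_len(nrow(df)), function(i)
    pain_assessment(session = df$session[i],
                    followup_months = df$followup_months[i],
                    nrs = df$nrs[i],
                    descriptor_scores = as.numeric(df[i, desc_cols]),
                    wpd_distribution = as.numeric(df[i, dist_cols]),
                    hours_slept = df$hours_slept[i]))
  pain_timeline(assessments)
}
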