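#' Segmentation specification for signal treatment
#'
#' Controls the three signal-treatment steps: bilateral trimming of each
#' contraction, concatenation, and overlapping-window segmentation. Defaults
#' are the standard pipeline constants: discard 15% of the contraction at each
#' end, then cut 200 ms windows advanced by 50 ms.
#'
#' Two window-count conventions are provided. `"closed_form"` enumerates every
#' full window: `n = floor((L - w) / inc) + 1`. `"drop_ends"` (the pipeline
#' default) additionally drops the two end-aligned windows, giving
#' `closed_form - 2`; on the default protocol (8.4 s of concatenated signal at
#' 2 kHz) this yields the canonical 163 windows per movement where the closed
#' form yields 165.
#'
#' @param trim_fraction fraction discarded at each end of a contraction,
#'   in [0, 0.5)
#' @param window_ms analysis window length, milliseconds
#' @param increment_ms window advance, milliseconds (0 < increment <= window)
#' @param convention `"drop_ends"` (default) or `"closed_form"`
#' @return object of class `segmentation_spec`
#' @export
segmentation_spec <- function(trim_fraction = 0.15, window_ms = 200,
                              increment_ms = 50,
                              convention = c("drop_ends", "closed_form")) {
  convention <- match.arg(convention)
  check_scalar_num(trim_fraction, "trim_fraction", lower = 0)
  if (trim_fraction >= 0.5)
    stop_invalid("trim_fraction", "must be < 0.5")
  check_scalar_num(window_ms, "window_ms", lower = 0, strict_lower = TRUE)
  check_scalar_num(increment_ms, "increment_ms", lower = 0, strict_lower = TRUE)
  if (increment_ms > window_ms)
    stop_invalid("increment_ms", "must be <= window_ms")
  structure(list(trim_fraction = trim_fraction, window_ms = window_ms,
                 increment_ms = increment_ms, convention = convention),
            class = "segmentation_spec")
}

#' Trim contraction (or rest) segments of a session
#'
#' Discards `trim_fraction` of the samples at the beginning and at the end of
#' each interval, keeping the centered remainder; a 4 s contraction trimmed at
#' 15% yields a 2.8 s segment (5600 samples at 2 kHz). Sample counts are
#' floored after multiplication.
#'
#' @param session an `emg_session`
#' @param spec a [segmentation_spec()]
#' @param what `"contraction"` (the recorded ranges) or `"rest"` (the
#'   inter-contraction intervals, trimmed by the same rule; used to build the
#'   rest class)
#' @return named list (one element per movement, or a single `"rest"`
#'   element) of lists of trimmed signal matrices
#' @export
trim_contractions <- function(session, spec = segmentation_spec(),
                              what = c("contraction", "rest")) {
  what <- match.arg(what)
  validate_session(session)
  r <- session$ranges[order(session$ranges$start), ]
  sig <- session$signal
  if (what == "rest") {
    # rest intervals follow each contraction up to the next range (or the
    # protocol's rest duration at the session end)
    n_rest <- round(session$protocol$rest_s * session$protocol$sampling_rate)
    if (n_rest == 0) return(list(rest = list()))
    starts <- r$end
    ends <- pmin(r$end + n_rest, nrow(sig))
    segs <- lapply(seq_along(starts), function(i)
      trim_interval(sig, starts[i], ends[i], spec$trim_fraction))
    return(list(rest = segs))
  }
  out <- lapply(session$protocol$movements, function(m) {
    rows <- which(r$movement == m)
    lapply(rows, function(i)
      trim_interval(sig, r$start[i], r$end[i], spec$trim_fraction))
  })
  names(out) <- session$protocol$movements
  out
}

# [start, end) 0-based half-open; keep the centered 1 - 2*tf fraction.
trim_interval <- function(sig, start, end, trim_fraction) {
  n <- end - start
  n_trim <- floor(n * trim_fraction)
  sig[(start + n_trim + 1):(end - n_trim), , drop = FALSE]
}

#' Concatenate trimmed segments of one movement
#'
#' Stacks the trimmed repetitions in time; three 2.8 s segments give 8.4 s
#' (16800 samples at 2 kHz) of contraction signal. Boundary sample indices
#' (0-based, half-open) are attached as the `"boundaries"` attribute.
#'
#' @param segments list of signal matrices with equal channel counts
#' @return one signal matrix
#' @export
concatenate_movement <- function(segments) {
  if (length(segments) < 1) stop_invalid("segments", "need at least one segment")
  ncs <- vapply(segments, ncol, integer(1))
  if (length(unique(ncs)) != 1)
    stop_invalid("segments", "channel counts differ across segments")
  out <- do.call(rbind, segments)
  ends <- cumsum(vapply(segments, nrow, integer(1)))
  attr(out, "boundaries") <- data.frame(start = c(0L, ends[-length(ends)]),
                                        end = ends)
  out
}

#' Segment a signal into overlapping analysis windows
#'
#' Cuts fixed-length windows advanced by a fixed increment over the
#' concatenated per-movement signal. Window positions are 0-based half-open
#' sample intervals; milliseconds convert to samples by flooring.
#'
#' @param signal numeric matrix (samples x channels)
#' @param spec a [segmentation_spec()]; `spec$convention` picks the count rule
#' @param fs sampling rate, samples/s
#' @param label class label attached to every window
#' @return a `window_set`: list with `windows` (data.frame `label`, `start`,
#'   `end`), `signals` (named list of source matrices), `window_samples`,
#'   `fs`
#' @export
segment_windows <- function(signal, spec = segmentation_spec(), fs = 2000,
                            label = "signal") {
  w <- floor(spec$window_ms * fs / 1000)
  inc <- floor(spec$increment_ms * fs / 1000)
  L <- nrow(signal)
  if (L < w) stop_invalid("signal", sprintf("%d samples is shorter than one %d-sample window", L, w))
  n_cf <- floor((L - w) / inc) + 1
  starts <- (seq_len(n_cf) - 1L) * inc
  if (spec$convention == "drop_ends") {
    if (n_cf < 3)
      stop_invalid("signal", "too short for the drop_ends convention (needs >= 3 closed-form windows)")
    starts <- starts[-c(1L, n_cf)]
  }
  wins <- data.frame(label = label, start = starts, end = starts + w)
  sigs <- stats::setNames(list(signal), label)
  structure(list(windows = wins, signals = sigs, window_samples = w, fs = fs),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  tab <- table(x$windows$label)
  cat(sprintf("<window_set> %d windows of %d samples over %d class(es): %s\n",
              nrow(x$windows), x$window_samples, length(tab),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Full signal treatment of a session
#'
#' Applies trimming, per-movement concatenation and windowing to every
#' movement of a session (and, optionally, to the rest intervals, building a
#' `"rest"` class the same way), returning one combined `window_set`.
#'
#' @param session an `emg_session`
#' @param spec a [segmentation_spec()]
#' @param include_rest build a rest class from the rest intervals
#'   (default `TRUE`; the standard task is 8 movements + rest = 9 classes)
#' @param rest_label label for the rest class
#' @param rest_intervals `"balanced"` (default) uses the first
#'   `n_repetitions` rest intervals so the rest class carries the same signal
#'   duration — hence the same window count — as each movement class; `"all"`
#'   uses every rest interval
#' @return a `window_set` spanning all classes
#' @export
windows_from_session <- function(session, spec = segmentation_spec(),
                                 include_rest = TRUE, rest_label = "rest",
                                 rest_intervals = c("balanced", "all")) {
  rest_intervals <- match.arg(rest_intervals)
  fs <- session$protocol$sampling_rate
  trimmed <- trim_contractions(session, spec, "contraction")
  if (include_rest) {
    rest <- trim_contractions(session, spec, "rest")
    if (rest_intervals == "balanced")
      rest$rest <- rest$rest[seq_len(min(session$protocol$n_repetitions,
                                         length(rest$rest)))]
    names(rest) <- rest_label
    trimmed <- c(trimmed, rest)
  }
  parts <- lapply(names(trimmed), function(lbl)
    segment_windows(concatenate_movement(trimmed[[lbl]]), spec, fs, lbl))
  ws <- parts[[1]]
  for (p in parts[-1]) {
    ws$windows <- rbind(ws$windows, p$windows)
    ws$signals <- c(ws$signals, p$signals)
  }
  ws
}
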