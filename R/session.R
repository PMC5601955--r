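#' Recording-protocol specification
#'
#' Describes the acquisition protocol of an sEMG recording session: sampling,
#' channel count, the ordered movement list, and the repetition timing. The
#' defaults reproduce a standard non-weight-bearing lower-limb protocol:
#' 16 channels sampled at 2 kHz with 16-bit resolution and an amplifier gain
#' of 200, eight movements, each recorded as three consecutive 4 s
#' contractions separated by 4 s of rest.
#'
#' @param sampling_rate samples per second (> 0)
#' @param n_channels number of recording channels (>= 1)
#' @param bit_depth ADC resolution in bits
#' @param movements ordered character vector of unique movement labels
#' @param n_repetitions contraction repetitions per movement (>= 1)
#' @param contraction_s contraction duration, seconds (> 0)
#' @param rest_s rest duration after each contraction, seconds (>= 0)
#' @param gain amplifier gain (dimensionless); stored as metadata, the signal
#'   itself is kept in volts after gain
#' @return an object of class `protocol_spec`
#' @examples
#' p <- protocol_spec()
#' session_duration_s(p)  # 192 s for the default protocol
#' @export
protocol_spec <- function(sampling_rate = 2000,
                          n_channels = 16,
                          bit_depth = 16,
                          movements = lower_limb_movements(),
                          n_repetitions = 3,
                          contraction_s = 4,
                          rest_s = 4,
                          gain = 200) {
  check_scalar_num(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  check_scalar_num(n_channels, "n_channels", lower = 1, integer = TRUE)
  check_scalar_num(bit_depth, "bit_depth", lower = 1, integer = TRUE)
  check_scalar_num(n_repetitions, "n_repetitions", lower = 1, integer = TRUE)
  check_scalar_num(contraction_s, "contraction_s", lower = 0, strict_lower = TRUE)
  check_scalar_num(rest_s, "rest_s", lower = 0)
  check_scalar_num(gain, "gain", lower = 0, strict_lower = TRUE)
  if (!is.character(movements) || length(movements) == 0)
    stop_invalid("movements", "must be a non-empty character vector")
  if (anyDuplicated(movements)) stop_invalid("movements", "labels must be unique")
  structure(
    list(sampling_rate = sampling_rate, n_channels = as.integer(n_channels),
         bit_depth = as.integer(bit_depth), movements = movements,
         n_repetitions = as.integer(n_repetitions),
         contraction_s = contraction_s, rest_s = rest_s, gain = gain),
    class = "protocol_spec")
}

#' The eight default non-weight-bearing lower-limb movements
#' @return character vector of length 8
#' @export
lower_limb_movements <- function() {
  c("knee_flexion", "knee_extension",
    "ankle_plantarflexion", "ankle_dorsiflexion",
    "hip_rotation_medial", "hip_rotation_lateral",
    "tibial_rotation_medial", "tibial_rotation_lateral")
}

#' Total session duration implied by a protocol
#' @param protocol a [protocol_spec()]
#' @return duration in seconds
#' @export
session_duration_s <- function(protocol) {
  length(protocol$movements) * protocol$n_repetitions *
    (protocol$contraction_s + protocol$rest_s)
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("<protocol_spec> %d movements x %d reps (%g s + %g s rest), %d ch @ %g Hz, %d-bit, gain %g\n",
              length(x$movements), x$n_repetitions, x$contraction_s, x$rest_s,
              x$n_channels, x$sampling_rate, x$bit_depth, x$gain))
  invisible(x)
}

#' Construct an EMG recording session
#'
#' Bundles a multichannel signal matrix with its protocol and the
#' per-repetition contraction ranges. Sample ranges are 0-based half-open
#' intervals `[start, end)` into the signal rows, so windowing and trimming
#' arithmetic is unambiguous.
#'
#' @param protocol a [protocol_spec()]
#' @param signal numeric matrix, samples x channels, in volts (post-gain)
#' @param ranges data.frame with columns `movement`, `repetition`, `start`,
#'   `end` (0-based half-open sample intervals), one row per contraction
#' @param provenance free-text provenance tag (e.g. `"synthetic seed=1"`)
#' @return object of class `emg_session`
#' @export
emg_session <- function(protocol, signal, ranges, provenance = "unspecified") {
  s <- structure(list(protocol = protocol, signal = signal, ranges = ranges,
                      provenance = provenance),
                 class = "emg_session")
  validate_session(s)
  s
}

#' Validate an EMG session against its protocol invariants
#'
#' Checks signal shape, contraction-range count, bounds, ordering and
#' non-overlap. Called by [emg_session()]; exported because readers of
#' external bundles use it too.
#'
#' @param session an `emg_session`
#' @return the session, invisibly; errors name the violated field
#' @export
validate_session <- function(session) {
  p <- session$protocol
  sig <- session$signal
  if (!is.matrix(sig) || !is.numeric(sig))
    stop_invalid("signal", "must be a numeric matrix")
  n_expected <- round(session_duration_s(p) * p$sampling_rate)
  if (nrow(sig) != n_expected)
    stop_invalid("signal", sprintf("has %d samples but the protocol implies %d",
                                   nrow(sig), n_expected))
  if (ncol(sig) != p$n_channels)
    stop_invalid("signal", sprintf("has %d channels but protocol declares %d",
                                   ncol(sig), p$n_channels))
  r <- session$ranges
  need <- c("movement", "repetition", "start", "end")
  if (!is.data.frame(r) || !all(need %in% names(r)))
    stop_invalid("ranges", "must be a data.frame with movement/repetition/start/end")
  if (nrow(r) != length(p$movements) * p$n_repetitions)
    stop_invalid("ranges", sprintf("%d contraction ranges; protocol implies %d",
                                   nrow(r), length(p$movements) * p$n_repetitions))
  if (!all(r$movement %in% p$movements))
    stop_invalid("ranges", "movement labels not all in the protocol")
  if (any(r$start < 0) || any(r$end > nrow(sig)) || any(r$end <= r$start))
    stop_invalid("ranges", "intervals must satisfy 0 <= start < end <= n_samples")
  tab <- table(factor(r$movement, levels = p$movements))
  if (any(tab != p$n_repetitions))
    stop_invalid("ranges", "each movement must have exactly n_repetitions ranges")
  o <- order(r$start)
  if (any(r$end[o][-nrow(r)] > r$start[o][-1]))
    stop_invalid("ranges", "contraction ranges overlap")
  invisible(session)
}

#' @export
print.emg_session <- function(x, ...) {
  cat(sprintf("<emg_session> %d samples x %d ch (%g s @ %g Hz), %d contraction ranges\n  provenance: %s\n",
              nrow(x$signal), ncol(x$signal),
              nrow(x$signal) / x$protocol$sampling_rate,
              x$protocol$sampling_rate, nrow(x$ranges), x$provenance))
  invisible(x)
}

#' Keep a subset of channels
#'
#' Returns a new session holding only the requested channels (1-based
#' indices), in the given order, with the protocol metadata updated. The
#' 8-channel condition of a 16-channel untargeted recording is the equally
#' spaced subset `c(1, 3, 5, ..., 15)`.
#'
#' @param session an `emg_session`
#' @param channel_indices unique 1-based channel indices
#' @return an `emg_session` with `length(channel_indices)` channels
#' @examples
#' # s8 <- select_channels(s16, seq(1, 15, by = 2))
#' @export
select_channels <- function(session, channel_indices) {
  nc <- session$protocol$n_channels
  if (length(channel_indices) == 0) stop_invalid("channel_indices", "must be non-empty")
  if (any(channel_indices != round(channel_indices)) ||
      any(channel_indices < 1) || any(channel_indices > nc))
    stop_invalid("channel_indices", sprintf("must be integers in 1..%d", nc))
  if (anyDuplicated(channel_indices))
    stop_invalid("channel_indices", "must be unique")
  p <- session$protocol
  p$n_channels <- length(channel_indices)
  emg_session(p, session$signal[, channel_indices, drop = FALSE], session$ranges,
              provenance = paste0(session$provenance, " | channels [",
                                  paste(channel_indices, collapse = ","), "]"))
}
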