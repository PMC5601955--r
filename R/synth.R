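#' Movement-specific spatial activation model for synthetic sEMG
#'
#' Generates the activation matrix (movements x channels, weights in [0, 1])
#' that drives the synthetic session generator, together with the effort and
#' noise parameters of the simulated subject. `overlap` interpolates linearly
#' between a seeded set of mutually distinguishable per-movement patterns
#' (`overlap = 0`) and one common pattern shared by every movement
#' (`overlap = 1`), which makes downstream class separability tunable from
#' easy to impossible.
#'
#' @param n_movements number of movement classes (>= 1)
#' @param n_channels number of channels (>= 1)
#' @param overlap similarity between movement patterns, in [0, 1]
#' @param seed RNG seed; the model is deterministic for a fixed seed
#' @param baseline_noise_rms RMS of the electrode-referred (pre-gain) baseline
#'   noise in volts; default 5 uV, a typical surface-recording noise floor
#' @param mvc_fraction effort level as a fraction of maximal voluntary
#'   contraction; default 0.7 (subjects contract at ~70% MVC)
#' @param ramp_fraction fraction of the contraction spent ramping up (and
#'   again down); default 0.15, modelling smooth, jerk-free contractions
#' @param mvc_rms electrode-referred RMS in volts of a fully activated channel
#'   at 100% MVC; default 2 mV, a realistic surface-EMG amplitude
#' @return an object of class `activation_model`
#' @export
make_activation_matrix <- function(n_movements, n_channels, overlap = 0,
                                   seed = 1,
                                   baseline_noise_rms = 5e-6,
                                   mvc_fraction = 0.7,
                                   ramp_fraction = 0.15,
                                   mvc_rms = 2e-3) {
  check_scalar_num(n_movements, "n_movements", lower = 1, integer = TRUE)
  check_scalar_num(n_channels, "n_channels", lower = 1, integer = TRUE)
  check_scalar_num(overlap, "overlap", lower = 0, upper = 1)
  check_scalar_num(baseline_noise_rms, "baseline_noise_rms", lower = 0)
  check_scalar_num(mvc_fraction, "mvc_fraction", lower = 0, strict_lower = TRUE)
  check_scalar_num(ramp_fraction, "ramp_fraction", lower = 0, upper = 0.5)
  check_scalar_num(mvc_rms, "mvc_rms", lower = 0, strict_lower = TRUE)

  act <- with_seed(seed, {
    # Squared uniforms give sparse-ish, clearly distinct spatial patterns:
    # expected pairwise row cosine ~ 0.56, far from collinear.
    distinct <- matrix(stats::runif(n_movements * n_channels)^2,
                       nrow = n_movements)
    distinct <- distinct / apply(distinct, 1, max)
    common <- stats::runif(n_channels)^2
    common <- common / max(common)
    (1 - overlap) * distinct +
      overlap * matrix(common, n_movements, n_channels, byrow = TRUE)
  })
  structure(
    list(activation = act, overlap = overlap, seed = seed,
         baseline_noise_rms = baseline_noise_rms,
         mvc_fraction = mvc_fraction, ramp_fraction = ramp_fraction,
         mvc_rms = mvc_rms),
    class = "activation_model")
}

#' @export
print.activation_model <- function(x, ...) {
  cat(sprintf("<activation_model> %d movements x %d channels, overlap %g, seed %s\n",
              nrow(x$activation), ncol(x$activation), x$overlap,
              format(x$seed)))
  invisible(x)
}

#' Amplifier front-end specification
#'
#' Models the analog/digital front-end of the acquisition system: a 1st-order
#' Butterworth high-pass at 1 Hz, a 3rd-order Butterworth low-pass at 750 Hz,
#' a gain of 200, and mid-tread 16-bit quantization over a symmetric
#' full-scale range (default +/- 2.5 V post-gain).
#'
#' @param hp_order,hp_cutoff_hz high-pass order and cutoff
#' @param lp_order,lp_cutoff_hz low-pass order and cutoff
#' @param gain amplifier gain
#' @param bits quantizer resolution
#' @param fullscale_v half-range of the quantizer in volts (post-gain)
#' @return object of class `frontend_spec`
#' @export
frontend_spec <- function(hp_order = 1, hp_cutoff_hz = 1,
                          lp_order = 3, lp_cutoff_hz = 750,
                          gain = 200, bits = 16, fullscale_v = 2.5) {
  check_scalar_num(hp_order, "hp_order", lower = 1, integer = TRUE)
  check_scalar_num(lp_order, "lp_order", lower = 1, integer = TRUE)
  check_scalar_num(hp_cutoff_hz, "hp_cutoff_hz", lower = 0, strict_lower = TRUE)
  check_scalar_num(lp_cutoff_hz, "lp_cutoff_hz", lower = 0, strict_lower = TRUE)
  check_scalar_num(gain, "gain", lower = 0, strict_lower = TRUE)
  check_scalar_num(bits, "bits", lower = 2, integer = TRUE)
  check_scalar_num(fullscale_v, "fullscale_v", lower = 0, strict_lower = TRUE)
  structure(list(hp_order = hp_order, hp_cutoff_hz = hp_cutoff_hz,
                 lp_order = lp_order, lp_cutoff_hz = lp_cutoff_hz,
                 gain = gain, bits = as.integer(bits),
                 fullscale_v = fullscale_v),
            class = "frontend_spec")
}

#' Mid-tread quantization
#'
#' Rounds to the nearest of `2^bits` uniformly spaced levels spanning
#' `[-fullscale, +fullscale)` (mid-tread: zero is a level). Values beyond the
#' extreme codes clip, with a warning.
#'
#' @param x numeric vector or matrix
#' @param bits resolution
#' @param fullscale_v half-range in volts
#' @return quantized values, same shape as `x`
#' @export
quantize_midtread <- function(x, bits, fullscale_v) {
  delta <- 2 * fullscale_v / 2^bits
  code <- round(x / delta)
  lo <- -2^(bits - 1)
  hi <- 2^(bits - 1) - 1
  n_clip <- sum(code < lo | code > hi)
  if (n_clip > 0)
    warning(sprintf("%d samples clipped at the quantizer full scale", n_clip))
  pmin(pmax(code, lo), hi) * delta
}

# Band-limited (band_hz) unit-RMS Gaussian carrier, one column per channel.
emg_carrier <- function(n_samples, n_channels, fs, band_hz = c(20, 450)) {
  w <- matrix(stats::rnorm(n_samples * n_channels), n_samples, n_channels)
  hp <- butter_design(2, band_hz[1], fs, "high")
  lp <- butter_design(4, band_hz[2], fs, "low")
  w <- iir_filter(lp$b, lp$a, iir_filter(hp$b, hp$a, w))
  sdev <- apply(w, 2, stats::sd)
  sdev[sdev == 0] <- 1
  sweep(w, 2, sdev, "/")
}

# Trapezoidal effort envelope over one contraction of n samples.
trapezoid_envelope <- function(n, ramp_fraction) {
  n_ramp <- floor(n * ramp_fraction)
  e <- rep(1, n)
  if (n_ramp > 0) {
    up <- seq_len(n_ramp) / n_ramp
    e[seq_len(n_ramp)] <- up
    e[n - n_ramp + seq_len(n_ramp)] <- rev(up)
  }
  e
}

#' Generate a synthetic EMG recording session
#'
#' Simulates the full recording protocol: for every movement, each contraction
#' repetition carries, on channel `c`, `activation[m, c] * mvc_fraction *`
#' trapezoidal envelope `*` a band-limited (20-450 Hz) zero-mean Gaussian
#' carrier of RMS `mvc_rms`, superposed on broadband baseline noise; rest
#' periods carry baseline noise only. The summed signal then passes the
#' front-end high-pass and low-pass filters, the amplifier gain, and mid-tread
#' quantization, and the contraction sample ranges are recorded as metadata.
#' Fully deterministic for a fixed seed.
#'
#' @param protocol a [protocol_spec()]
#' @param model an [make_activation_matrix()] model whose dimensions match the
#'   protocol's movements/channels
#' @param frontend a [frontend_spec()]
#' @param seed RNG seed; defaults to the model's seed
#' @param mixing optional row-stochastic channel-mixing matrix (channels x
#'   channels) emulating inter-electrode crosstalk; default `NULL` (off)
#' @return an `emg_session`
#' @export
generate_session <- function(protocol, model, frontend = frontend_spec(),
                             seed = model$seed, mixing = NULL) {
  fs <- protocol$sampling_rate
  if (frontend$lp_cutoff_hz >= fs / 2 || frontend$hp_cutoff_hz >= fs / 2)
    stop_invalid("frontend", "filter cutoffs must be below Nyquist")
  n_mov <- length(protocol$movements)
  n_ch <- protocol$n_channels
  if (nrow(model$activation) != n_mov || ncol(model$activation) != n_ch)
    stop_invalid("model", sprintf("activation is %d x %d; protocol implies %d x %d",
                                  nrow(model$activation), ncol(model$activation),
                                  n_mov, n_ch))
  if (!is.null(mixing)) {
    if (!is.matrix(mixing) || any(dim(mixing) != n_ch))
      stop_invalid("mixing", "must be an n_channels x n_channels matrix")
  }

  n_contr <- round(protocol$contraction_s * fs)
  n_rest <- round(protocol$rest_s * fs)
  n_block <- n_contr + n_rest
  n_total <- n_mov * protocol$n_repetitions * n_block

  # Per-sample envelope and movement index (0 during rest).
  env <- numeric(n_total)
  mov_idx <- integer(n_total)
  ranges <- vector("list", n_mov * protocol$n_repetitions)
  one_env <- trapezoid_envelope(n_contr, model$ramp_fraction)
  k <- 0L
  for (m in seq_len(n_mov)) {
    for (rep_i in seq_len(protocol$n_repetitions)) {
      k <- k + 1L
      start <- ((m - 1L) * protocol$n_repetitions + (rep_i - 1L)) * n_block
      idx <- start + seq_len(n_contr)
      env[idx] <- one_env
      mov_idx[idx] <- m
      ranges[[k]] <- data.frame(movement = protocol$movements[m],
                                repetition = rep_i,
                                start = start, end = start + n_contr)
    }
  }
  ranges <- do.call(rbind, ranges)

  sig <- with_seed(seed, {
    carrier <- emg_carrier(n_total, n_ch, fs)
    noise <- matrix(stats::rnorm(n_total * n_ch, sd = model$baseline_noise_rms),
                    n_total, n_ch)
    # activation per sample: 0 at rest, activation[m, ] during movement m
    act_ps <- matrix(0, n_total, n_ch)
    on_mov <- mov_idx > 0L
    act_ps[on_mov, ] <- model$activation[mov_idx[on_mov], , drop = FALSE]
    raw <- carrier * act_ps * (model$mvc_fraction * model$mvc_rms * env) + noise
    if (!is.null(mixing)) raw <- raw %*% t(mixing)
    hp <- butter_design(frontend$hp_order, frontend$hp_cutoff_hz, fs, "high")
    lp <- butter_design(frontend$lp_order, frontend$lp_cutoff_hz, fs, "low")
    filtered <- iir_filter(lp$b, lp$a, iir_filter(hp$b, hp$a, raw))
    quantize_midtread(filtered * frontend$gain, frontend$bits,
                      frontend$fullscale_v)
  })

  emg_session(protocol, sig, ranges,
              provenance = sprintf("synthetic seed=%s overlap=%g",
                                   format(seed), model$overlap))
}
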