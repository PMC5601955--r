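#' Digital Butterworth filter design
#'
#' Designs low-pass or high-pass Butterworth filters by bilinear transform of
#' the analog prototype (with frequency pre-warping), returning transfer
#' function coefficients in the usual `b` (numerator) / `a` (denominator)
#' convention.
#'
#' @param order filter order (>= 1)
#' @param cutoff_hz -3 dB cutoff frequency in Hz; must be below Nyquist
#' @param fs sampling rate in samples/s
#' @param type `"low"` or `"high"`
#' @return list with numeric vectors `b` and `a` (length `order + 1`,
#'   `a[1] == 1`)
#' @examples
#' co <- butter_design(3, 750, 2000, "low")
#' @export
butter_design <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  check_scalar_num(order, "order", lower = 1, integer = TRUE)
  check_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  check_scalar_num(cutoff_hz, "cutoff_hz", lower = 0, strict_lower = TRUE)
  if (cutoff_hz >= fs / 2)
    stop_invalid("cutoff_hz", sprintf("must be below the Nyquist frequency %g Hz", fs / 2))

  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # unit-circle LHP poles
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)                   # pre-warped analog cutoff
  if (type == "low") {
    poles <- wc * proto
    zeros <- complex(0)
    gain <- wc^order
  } else {
    poles <- wc / proto
    zeros <- rep(0 + 0i, order)
    gain <- 1
  }
  fs2 <- 2 * fs
  pd <- (fs2 + poles) / (fs2 - poles)
  zd <- c((fs2 + zeros) / (fs2 - zeros), rep(-1 + 0i, order - length(zeros)))
  kd <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  list(b = Re(kd * poly_from_roots(zd)), a = Re(poly_from_roots(pd)))
}

poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Apply an IIR filter (direct form, zero initial conditions)
#'
#' Causal filtering equivalent to the standard difference equation
#' `a[1] y[n] = sum(b * x[n - 0:nb]) - sum(a[-1] * y[n - 1:na])`.
#' Implemented as an FIR convolution followed by the recursive part, both via
#' [stats::filter()], so it is fast on long signals.
#'
#' @param b,a transfer-function coefficients (`a[1]` must be nonzero)
#' @param x numeric vector, or a matrix filtered column-wise
#' @return filtered signal, same shape as `x`
#' @export
iir_filter <- function(b, a, x) {
  if (a[1] == 0) stop_invalid("a", "a[1] must be nonzero")
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- iir_filter(b, a, x[, j])
    return(out)
  }
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  v <- x * b[1]
  if (nb > 1) {
    v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution", sides = 1)
    v <- as.numeric(v)[-seq_len(nb - 1)]
  }
  if (length(a) > 1) v <- stats::filter(v, -a[-1], method = "recursive")
  as.numeric(v)
}
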