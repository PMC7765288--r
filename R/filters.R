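# Butterworth band-pass design and zero-phase filtering.
#
# No DSP package is assumed: the design follows the textbook route
# (analog low-pass prototype -> low-pass-to-band-pass transform -> bilinear
# transform with frequency pre-warping), which for a given order and band is
# fully determined, so the filter is a testable contract rather than an
# opaque dependency.

#' Butterworth band-pass filter coefficients
#'
#' @param low,high band edges in Hz.
#' @param fs sampling rate in Hz; requires `high < fs/2`.
#' @param order analog prototype order (the digital band-pass has `2*order`
#'   poles). Default 4.
#' @return list with numerator `b` and denominator `a` (a\[1\] = 1).
#' @export
butter_bandpass <- function(low, high, fs, order = 4L) {
  stopifnot(low > 0, high > low, high < fs / 2)
  # analog prototype poles on the unit circle, left half-plane
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  gain <- 1

  # pre-warped band edges (fs normalised to 2 samples/s for the bilinear step)
  fs2 <- 2
  w1 <- 2 * fs2 * tan(pi * low / fs)
  w2 <- 2 * fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)

  # low-pass -> band-pass on poles/zeros
  p_lp <- p * bw / 2
  p_bp <- c(p_lp + sqrt(p_lp^2 - w0^2), p_lp - sqrt(p_lp^2 - w0^2))
  z_bp <- rep(0 + 0i, order)
  gain <- gain * bw^order

  # bilinear transform
  fs2x <- 2 * fs2
  z_d <- (fs2x + z_bp) / (fs2x - z_bp)
  p_d <- (fs2x + p_bp) / (fs2x - p_bp)
  gain_d <- gain * Re(prod(fs2x - z_bp) / prod(fs2x - p_bp))
  z_d <- c(z_d, rep(-1 + 0i, length(p_bp) - length(z_bp)))

  poly_from_roots <- function(r) {
    coefs <- 1 + 0i
    for (root in r) coefs <- c(coefs, 0) - c(0, coefs) * root
    coefs
  }
  b <- Re(gain_d * poly_from_roots(z_d))
  a <- Re(poly_from_roots(p_d))
  list(b = b / a[1], a = a / a[1])
}

iir_filter <- function(b, a, x) {
  # direct-form IIR: FIR part by convolution, then the recursion
  n <- length(x)
  xp <- c(rep(0, length(b) - 1L), x)
  fir <- stats::filter(xp, b, method = "convolution", sides = 1)
  fir <- as.numeric(fir)[length(b):(length(b) - 1L + n)]
  if (length(a) > 1L) {
    as.numeric(stats::filter(fir, -a[-1], method = "recursive"))
  } else {
    fir
  }
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and backward so the net phase response is zero,
#' with odd-symmetric edge extension to suppress start-up transients.
#'
#' @param b,a filter coefficients, e.g. from [butter_bandpass()].
#' @param x numeric signal (no NAs).
#' @return filtered signal, same length as `x`.
#' @export
filtfilt_zero_phase <- function(b, a, x) {
  stopifnot(!anyNA(x))
  n <- length(x)
  pad <- 3L * (max(length(a), length(b)) - 1L)
  if (n <= pad) stop("signal too short for the requested filter order")
  head_ext <- 2 * x[1] - x[(pad + 1L):2L]
  tail_ext <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xe <- c(head_ext, x, tail_ext)
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1L):(pad + n)]
}
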