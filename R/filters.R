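# Minimal DSP kernel: windowed-sinc FIR, Butterworth IIR, zero-phase
# application, analytic-signal magnitude, and band-limited resampling.
# Implemented here because no dedicated signal-processing package is a
# declared dependency; all routines are validated against closed-form
# frequency-response oracles in the test suite.

#' Windowed-sinc low-pass FIR design
#'
#' Linear-phase low-pass filter of even order `order` (`order + 1` taps),
#' Hann-windowed, normalized to unit DC gain.
#'
#' @param order Filter order (number of taps minus one); must be even so the
#'   filter has integer group delay.
#' @param cutoff_hz Cutoff frequency in Hz (-6 dB point of the windowed design).
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of `order + 1` filter taps.
#' @export
fir_lowpass <- function(order, cutoff_hz, fs) {
  stopifnot(order %% 2 == 0, order >= 2, cutoff_hz > 0, fs > 2 * cutoff_hz)
  m <- order / 2
  k <- seq(-m, m)
  fc <- cutoff_hz / fs
  h <- 2 * fc * sinc(2 * fc * k)
  w <- 0.5 + 0.5 * cos(pi * k / m) # Hann window over the taps
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Butterworth low-pass IIR design
#'
#' Classic analog Butterworth prototype mapped by the bilinear transform with
#' frequency prewarping; unit DC gain.
#'
#' @param order Filter order.
#' @param cutoff_hz -3 dB cutoff frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @return List with numerator `b` and denominator `a` coefficient vectors.
#' @export
butter_lowpass <- function(order, cutoff_hz, fs) {
  stopifnot(order >= 1, cutoff_hz > 0, fs > 2 * cutoff_hz)
  # prewarped analog cutoff
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  p_analog <- wc * complex(modulus = 1, argument = theta)
  # bilinear transform: z-pole = (2 fs + s) / (2 fs - s); zeros map to z = -1
  p_z <- (2 * fs + p_analog) / (2 * fs - p_analog)
  a <- Re(poly_from_roots(p_z))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  # normalize to unit gain at z = 1 (DC)
  b <- b * sum(a) / sum(b)
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# Single-pass IIR/FIR filtering with zero initial conditions.
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  if (nb > 1) {
    xp <- c(rep(0, nb - 1), x)
    v <- stats::filter(xp, b, method = "convolution", sides = 1)
    v <- as.numeric(v)[nb:length(xp)]
  } else {
    v <- b * x
  }
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase filtering (forward-backward)
#'
#' Applies the filter `(b, a)` forward and backward over odd-reflection-padded
#' data, cancelling the phase response. The effective amplitude response is
#' the squared magnitude of the single-pass filter.
#'
#' @param b,a Filter coefficient vectors (`a = 1` for FIR).
#' @param x Numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(b, a, x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  padlen <- 3 * (max(length(a), length(b)) - 1)
  if (padlen >= n) padlen <- n - 1
  if (padlen > 0) {
    front <- 2 * x[1] - x[seq(padlen + 1, 2)]
    back <- 2 * x[n] - x[seq(n - 1, n - padlen)]
    xp <- c(front, x, back)
  } else {
    xp <- x
  }
  y <- iir_filter(b, a, xp)
  y <- rev(iir_filter(b, a, rev(y)))
  y[seq(padlen + 1, padlen + n)]
}

#' Magnitude of the analytic signal
#'
#' FFT-based Hilbert envelope: `|x + i * H(x)|`.
#'
#' @param x Real-valued signal.
#' @return Nonnegative envelope, same length as `x`.
#' @export
hilbert_magnitude <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  if (n == 0L) return(numeric(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Resample a signal already band-limited far below both Nyquist rates.
# Integer decimation when the ratio is integral, otherwise linear
# interpolation on the target time grid (adequate because callers low-pass
# at 8 Hz before resampling to rates >= 100 Hz).
resample_signal <- function(x, fs_from, fs_to) {
  stopifnot(fs_from > 0, fs_to > 0)
  if (fs_from == fs_to) return(x)
  ratio <- fs_from / fs_to
  n_out <- floor(length(x) * fs_to / fs_from)
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- 1 + round(ratio) * (seq_len(n_out) - 1)
    return(x[idx])
  }
  t_out <- (seq_len(n_out) - 1) / fs_to
  t_in <- (seq_along(x) - 1) / fs_from
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}
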