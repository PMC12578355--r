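# Butterworth denoising: zero-phase (forward-backward) low-pass filtering.
#
# The filter design comes from signal::butter; the application is a
# direct-form-II-transposed IIR pass (compiled) run forward and backward with
# odd-reflection padding and steady-state initial conditions, so a constant
# input passes through exactly and edge transients decay inside the pad.

# Steady-state initial conditions for lfilter: with z = zi * x0 the filter
# output on a constant input x0 is immediately the DC-gain response.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (a[1] != 1) { b <- b / a[1]; a <- a / a[1] }
  if (n == 1) return(numeric(0))
  # Companion-form state matrix of the denominator.
  A <- rbind(-a[-1], cbind(diag(1, n - 2), rep(0, n - 2)))
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(diag(1, n - 1) - t(A), B))
}

# One-directional IIR filter with steady-state initialisation scaled to x[1].
lfilter_ss <- function(b, a, x) {
  zi <- lfilter_zi(b, a)
  lfilter_cpp(b, a, x, zi * x[1])
}

# Zero-phase application of an ARMA filter (b, a) with odd-reflection padding.
# `pad` extends the default 3*(ntaps-1) reflection when the filter's time
# constant is long relative to the signal (low cutoffs).
filtfilt_zp <- function(b, a, x, pad = NULL) {
  n <- length(x)
  ntaps <- max(length(a), length(b))
  pad <- min(n - 1L, as.integer(pad %||% (3L * (ntaps - 1L))))
  if (pad > 0) {
    left <- 2 * x[1] - x[seq(pad + 1, 2)]
    right <- 2 * x[n] - x[seq(n - 1, n - pad)]
    ext <- c(left, x, right)
  } else ext <- x
  y <- lfilter_ss(b, a, ext)
  y <- rev(lfilter_ss(b, a, rev(y)))
  if (pad > 0) y[seq(pad + 1, pad + n)] else y
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass filter and applies it forward and backward
#' (zero phase). The two passes square the magnitude response, so attenuation
#' in dB doubles: at the cutoff the amplitude ratio is -6.02 dB instead of the
#' single-pass -3.01 dB. The DC component is preserved and the output has the
#' same length as the input.
#'
#' @param samples numeric vector of signal samples.
#' @param sampling_rate sampling rate in Hz.
#' @param cutoff_hz cutoff frequency in Hz; must lie in (0, sampling_rate/2).
#' @param order filter order (>= 1), default 4.
#' @return filtered numeric vector, same length as `samples`.
#' @examples
#' x <- sin(2 * pi * 1 * seq(0, 10, by = 1 / 100))
#' y <- butterworth_lowpass(x, 100, cutoff_hz = 5)
#' @export
butterworth_lowpass <- function(samples, sampling_rate, cutoff_hz, order = 4) {
  if (!is.numeric(samples) || length(samples) < 2)
    stop_data("samples must be a numeric vector of length >= 2")
  if (cutoff_hz <= 0 || cutoff_hz >= sampling_rate / 2)
    stop_config("cutoff_hz must lie strictly between 0 and the Nyquist rate (",
                sampling_rate / 2, " Hz)")
  if (order < 1) stop_config("order must be >= 1")
  bf <- signal::butter(order, cutoff_hz / (sampling_rate / 2), type = "low")
  # pad over ~1.5 cutoff periods so start-up transients decay inside the pad
  filtfilt_zp(bf$b, bf$a, samples,
              pad = max(3 * order, ceiling(1.5 / cutoff_hz * sampling_rate)))
}

# Zero-phase Butterworth band-pass (used by the ECG R-peak detector).
butterworth_bandpass <- function(samples, sampling_rate, low_hz, high_hz,
                                 order = 2) {
  nyq <- sampling_rate / 2
  if (low_hz <= 0 || high_hz >= nyq || low_hz >= high_hz)
    stop_config("band edges must satisfy 0 < low < high < Nyquist")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  filtfilt_zp(bf$b, bf$a, samples)
}
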