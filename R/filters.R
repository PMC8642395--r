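#' Zero-phase band-pass filtering
#'
#' All band-pass filtering in the package (the 4-6.67 Hz cuff-oscillation
#' band and the 50-band Korotkoff filter bank) is zero-phase: the signal
#' spectrum is multiplied by the squared magnitude response of a 4-pole
#' Butterworth band-pass, which is exactly the magnitude response of
#' forward-backward (filtfilt) filtering but with no transient and no
#' numerical ill-conditioning at very narrow relative bands. Peak times are
#' therefore never shifted by filtering.
#'
#' @name zero-phase-filtering
#' @keywords internal
NULL

# |H(f)|^2 for an order-n Butterworth band-pass prototype (a 2*order-pole
# band-pass); applying the filter forward and backward multiplies the
# amplitude spectrum by this.
bp_zero_phase_gain <- function(f, f1, f2, order = 2) {
  x <- ifelse(f == 0, Inf, (f^2 - f1 * f2) / (f * (f2 - f1)))
  1 / (1 + x^(2 * order))
}

# Apply a zero-phase band-pass to a real series by spectral multiplication.
fft_bandpass <- function(x, fs, f1, f2, order = 2) {
  n <- length(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)               # two-sided |frequency|
  g <- bp_zero_phase_gain(f, f1, f2, order)
  Re(fft(fft(x) * g, inverse = TRUE)) / n
}

# Zero-phase low-pass (Butterworth magnitude squared), used for envelopes.
fft_lowpass <- function(x, fs, fc, order = 2) {
  n <- length(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  g <- 1 / (1 + (f / fc)^(2 * order))
  Re(fft(fft(x) * g, inverse = TRUE)) / n
}

# Smoothed amplitude envelope of the Korotkoff band (25-200 Hz):
# band-pass, rectify, 20 Hz zero-phase low-pass.
ksound_envelope <- function(x, fs, band = c(25, 200), smooth_hz = 20) {
  bp <- fft_bandpass(x, fs, band[1], band[2])
  pmax(fft_lowpass(abs(bp), fs, smooth_hz), 0)
}
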