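# Acquisition-style low-pass filtering.
#
# Patch-clamp amplifiers condition the current signal with an analog Bessel
# low-pass before digitisation. We mimic that stage with a 4-pole Bessel-type
# filter applied forward only (causal), so synthetic traces carry the same
# small group delay a recorded trace would.

# 4th-order reversed Bessel polynomial: s^4 + 10 s^3 + 45 s^2 + 105 s + 105.
bessel4_prototype_poles <- function() {
  p <- polyroot(c(105, 105, 45, 10, 1))
  # normalize so |H(j*1)|^2 = 1/2 (-3 dB at 1 rad/s)
  mag2 <- function(w) {
    h <- prod(Mod(-p)) / prod(Mod(complex(imaginary = w) - p))
    h^2
  }
  w3db <- uniroot(function(w) mag2(w) - 0.5, c(0.5, 5), tol = 1e-12)$root
  p / w3db
}

#' Design a 4-pole Bessel-type low-pass filter
#'
#' Returns digital filter coefficients (via bilinear transform with cutoff
#' pre-warping) for the causal 4-pole Bessel low-pass used throughout the
#' package to emulate the acquisition chain.
#'
#' @param cutoff_khz -3 dB cutoff frequency in kHz.
#' @param sampling_khz Sampling rate in kHz; must exceed `2 * cutoff_khz`.
#' @return A `signal::Arma` filter object.
#' @keywords internal
bessel_lowpass <- function(cutoff_khz, sampling_khz) {
  if (!is.finite(cutoff_khz) || !is.finite(sampling_khz) || cutoff_khz <= 0) {
    abort("`cutoff_khz` and `sampling_khz` must be positive and finite.")
  }
  if (sampling_khz <= 2 * cutoff_khz) {
    abort("`sampling_khz` must exceed twice `cutoff_khz` (Nyquist).")
  }
  fs <- sampling_khz * 1000
  fc <- cutoff_khz * 1000
  wc <- 2 * fs * tan(pi * fc / fs)  # pre-warped analog cutoff (rad/s)
  p <- bessel4_prototype_poles() * wc
  g <- Re(prod(-p))                 # unity DC gain
  zpg <- signal::bilinear(Sz = complex(0), Sp = p, Sg = g, T = 1 / fs)
  signal::as.Arma(zpg)
}

#' Apply the acquisition low-pass to a numeric trace
#'
#' Forward (causal) filtering only; initial conditions are set from the first
#' sample so a constant input maps to the same constant without a start-up
#' transient.
#'
#' @param x Numeric vector (a current or stimulus trace).
#' @inheritParams bessel_lowpass
#' @return Filtered numeric vector of the same length.
#' @export
filter_trace <- function(x, cutoff_khz, sampling_khz) {
  flt <- bessel_lowpass(cutoff_khz, sampling_khz)
  # subtract/re-add the first sample: steps at t=0 are part of the signal,
  # but the pre-recording DC level should not ring the filter
  x0 <- x[1]
  y <- signal::filter(flt, x - x0)
  as.numeric(y) + x0
}

# cache of characterized group delays, keyed by "fs|fc"
.delay_cache <- new.env(parent = emptyenv())

#' Characterized onset delay of the acquisition filter
#'
#' The delay is measured empirically on a unit step: the time at which the
#' causal filter's step response first exceeds 5% of its final value (the
#' filter's dead time). Onset latencies measured on filtered traces subtract
#' this delay, since threshold crossings are detected low on the rising edge.
#'
#' @inheritParams bessel_lowpass
#' @return Delay in milliseconds.
#' @export
filter_delay_ms <- function(cutoff_khz, sampling_khz) {
  key <- paste(sampling_khz, cutoff_khz, sep = "|")
  hit <- .delay_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- max(64L, ceiling(20 * sampling_khz / cutoff_khz))
  step <- c(rep(0, 8), rep(1, n))
  y <- filter_trace(step, cutoff_khz, sampling_khz)
  idx <- which(y >= 0.05)[1]
  delay <- (idx - 9L) / sampling_khz  # ms; step occurs at sample 9
  .delay_cache[[key]] <- delay
  delay
}
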