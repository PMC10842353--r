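#' Difference-of-exponentials transient kernel
#'
#' Canonical shape of a fluorescence transient: a rising exponential with time
#' constant `tau_rise` and a decaying exponential with time constant
#' `tau_decay`, normalized so the peak value is exactly 1. Used for evoked and
#' spontaneous transients and for the micro-transients that make up the
#' shot-noise baseline.
#'
#' @param t Numeric vector of times (s) relative to event onset. Values `< 0`
#'   evaluate to 0.
#' @param tau_rise Rise time constant (s), must be `< tau_decay`.
#' @param tau_decay Decay time constant (s).
#' @return Numeric vector of kernel values with unit peak.
#' @examples
#' k <- transient_kernel(seq(0, 2, by = 0.01), 0.05, 0.5)
#' max(k) # 1
#' @export
transient_kernel <- function(t, tau_rise, tau_decay) {
  stopifnot(tau_rise > 0, tau_decay > 0)
  if (tau_rise >= tau_decay) {
    stop("tau_rise must be smaller than tau_decay")
  }
  peak <- kernel_peak(tau_rise, tau_decay)
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  out[pos] <- (exp(-tp / tau_decay) - exp(-tp / tau_rise)) / peak
  out
}

#' Time and value of the kernel peak (closed form)
#' @noRd
kernel_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

kernel_peak <- function(tau_rise, tau_decay) {
  tp <- kernel_peak_time(tau_rise, tau_decay)
  exp(-tp / tau_decay) - exp(-tp / tau_rise)
}

#' Integral of the unit-peak kernel over [0, Inf), in seconds
#'
#' The kernel "occupancy": how long an event keeps a sensor fluorescent,
#' expressed as peak-equivalent seconds. Enters the duty-cycle model of
#' use-dependent photobleaching.
#'
#' @inheritParams transient_kernel
#' @return Scalar, seconds.
#' @export
kernel_area <- function(tau_rise, tau_decay) {
  (tau_decay - tau_rise) / kernel_peak(tau_rise, tau_decay)
}

#' Integral of the squared unit-peak kernel (Campbell's theorem helper)
#' @noRd
kernel_l2 <- function(tau_rise, tau_decay) {
  p <- kernel_peak(tau_rise, tau_decay)
  (tau_decay / 2 + tau_rise / 2 -
    2 * tau_rise * tau_decay / (tau_rise + tau_decay)) / p^2
}

#' Kernel sampled on the frame grid
#'
#' Samples the unit-peak kernel at frame times `0, 1/rate, ...` until it has
#' decayed below `cutoff` of its peak (after the peak time).
#' @noRd
kernel_frames <- function(tau_rise, tau_decay, rate, cutoff = 1e-3) {
  t_end <- kernel_peak_time(tau_rise, tau_decay) - tau_decay * log(cutoff)
  n <- max(2L, ceiling(t_end * rate))
  transient_kernel((seq_len(n) - 1) / rate, tau_rise, tau_decay)
}
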