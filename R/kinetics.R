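#' Per-event amplitude and kinetics
#'
#' For each detected event: amplitude above the frozen baseline (dF, and
#' normalized dF/F0 with the frozen baseline as F0), 20-80% rise time on the
#' rising limb (linear interpolation between frames), and decay time constant
#' from a single-exponential least-squares fit starting at the peak and ending
#' at the earlier of peak + `fit_window` or the next event's onset. If the fit
#' fails to converge the time to half amplitude is used instead (converted to
#' an equivalent tau by dividing by log 2, flagged in `decay_method`). Events
#' whose peak sits at the trace end get `NA` decay and are flagged truncated.
#'
#' Amplitudes are by default taken from `s`; when the unsmoothed detrended
#' trace is supplied as `amp_trace`, the amplitude is the raw maximum over the
#' event extent instead — the pipeline default, since a 3-point moving average
#' attenuates the peak of a fast-rising transient by several percent while
#' the raw peak at high SNR is nearly unbiased.
#'
#' @param s Smoothed, detrended trace the events were detected on.
#' @param rate Sampling rate, frames/s.
#' @param events Detection table from [detect_events()].
#' @param time Frame start times, s.
#' @param fit_window Maximum decay-fit span after the peak, s.
#' @param amp_trace Optional unsmoothed detrended trace for amplitude
#'   measurement.
#' @return `data.frame` with columns `amplitude_df`, `amplitude_dff`,
#'   `rise_s`, `decay_s`, `decay_method` (`"fit"`, `"half"`, or `NA`).
#' @export
event_kinetics <- function(s, rate, events, time = NULL, fit_window = 2,
                           amp_trace = NULL) {
  n <- length(s)
  if (is.null(time)) time <- (seq_len(n) - 1) / rate
  m <- nrow(events)
  out <- data.frame(amplitude_df = numeric(m), amplitude_dff = numeric(m),
                    rise_s = rep(NA_real_, m), decay_s = rep(NA_real_, m),
                    decay_method = rep(NA_character_, m))
  if (m == 0) return(out)
  for (k in seq_len(m)) {
    o <- events$onset_idx[k]; p <- events$peak_idx[k]
    fb <- events$frozen_baseline[k]
    amp <- s[p] - fb # smoothed amplitude drives rise/decay landmarks
    amp_out <- if (is.null(amp_trace)) {
      amp
    } else {
      max(amp_trace[o:events$end_idx[k]]) - fb
    }
    out$amplitude_df[k] <- amp_out
    out$amplitude_dff[k] <- amp_out / fb
    out$rise_s[k] <- rise_time(s, time, o, p, fb, amp)

    last <- min(n, p + round(fit_window * rate))
    if (k < m) last <- min(last, events$onset_idx[k + 1] - 1L)
    if (p >= n || last - p < 2) next # peak at trace end: decay undefined
    dk <- decay_tau(time[p:last] - time[p], s[p:last] - fb, amp)
    out$decay_s[k] <- dk$tau
    out$decay_method[k] <- dk$method
  }
  out
}

#' 20-80% rise time with linear interpolation
#' @noRd
rise_time <- function(s, time, o, p, fb, amp) {
  if (p == o) return(min(diff(time[max(1, o - 1):p]), 0.1))
  v <- s[o:p] - fb
  t20 <- cross_time(time[o:p], v, 0.2 * amp)
  t80 <- cross_time(time[o:p], v, 0.8 * amp)
  max(t80 - t20, 0)
}

# last upward crossing of level before the segment maximum: walk back from
# the peak to the nearest frame below the level and interpolate. More robust
# to noise on the rising limb than the first crossing from the onset side.
cross_time <- function(tt, v, level) {
  n <- length(v)
  below <- which(v < level)
  below <- below[below < n]
  if (!length(below)) return(tt[1])
  i <- below[length(below)]
  frac <- (level - v[i]) / (v[i + 1] - v[i])
  tt[i] + frac * (tt[i + 1] - tt[i])
}

#' Exponential decay fit with time-to-half fallback
#' @noRd
decay_tau <- function(tt, y, amp) {
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-tt / tau),
                      start = list(A = amp, tau = max(tt[length(tt)] / 3, 0.1)),
                      control = minpack.lm::nls.lm.control(maxiter = 50)),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (!is.null(fit)) {
    tau <- stats::coef(fit)[["tau"]]
    # reject degenerate fits (flat tails can push tau to absurd values)
    if (is.finite(tau) && tau > 0 && tau <= 5 * max(tt)) {
      return(list(tau = tau, method = "fit"))
    }
  }
  # time to half amplitude, converted to an equivalent tau
  below <- which(y <= amp / 2)
  below <- below[below > 1]
  if (!length(below)) return(list(tau = NA_real_, method = NA_character_))
  i <- below[1]
  frac <- (y[i - 1] - amp / 2) / (y[i - 1] - y[i])
  t_half <- tt[i - 1] + frac * (tt[i] - tt[i - 1])
  list(tau = t_half / log(2), method = "half")
}

#' Event-triggered average waveform
#'
#' Averages frozen-baseline-subtracted trace segments aligned at event onset
#' across one or many ROIs — the averaged-event view used to compare class
#' kinetics, which suppresses the per-event measurement noise floor
#' (roughly one frame at 10 Hz).
#'
#' @param traces List of smoothed, detrended trace vectors.
#' @param events Combined detection table with columns `trace` (index into
#'   `traces`), `onset_idx` and `frozen_baseline`; pass the full table of all
#'   classes so isolation can be judged, and select with `class`.
#' @param rate Sampling rate, frames/s.
#' @param pre,post Seconds before/after onset to include; events too close to
#'   a trace edge are dropped.
#' @param class Optional class filter applied after the isolation check.
#' @param isolated Drop events with any other detected event inside their
#'   averaging window (default), so neighbouring tails do not contaminate the
#'   averaged shape.
#' @return List: `time` (s relative to onset), `wave` (mean waveform, F
#'   units above baseline), `n` (events averaged).
#' @export
event_triggered_average <- function(traces, events, rate, pre = 0.3,
                                    post = 2, class = NULL, isolated = TRUE) {
  a <- round(pre * rate); b <- round(post * rate)
  keep <- rep(TRUE, nrow(events))
  if (isolated && nrow(events) > 1) {
    for (k in seq_len(nrow(events))) {
      same <- events$trace == events$trace[k]
      d <- events$onset_idx[same] - events$onset_idx[k]
      keep[k] <- !any(d != 0 & d >= -(a + b) & d <= b)
    }
  }
  if (!is.null(class)) keep <- keep & events$class == class
  events <- events[keep, , drop = FALSE]
  segs <- list()
  for (k in seq_len(nrow(events))) {
    s <- traces[[events$trace[k]]]
    o <- events$onset_idx[k]
    if (o - a < 1 || o + b > length(s)) next
    segs[[length(segs) + 1L]] <- s[(o - a):(o + b)] - events$frozen_baseline[k]
  }
  if (!length(segs)) stop("no events with full windows to average")
  wave <- colMeans(do.call(rbind, segs))
  list(time = ((-a):b) / rate, wave = wave, n = length(segs))
}

#' Amplitude, rise and decay of an averaged waveform
#'
#' @param eta Result of [event_triggered_average()].
#' @param rate Sampling rate, frames/s.
#' @param fit_window Decay-fit span after the peak, s.
#' @return One-row `data.frame`: `amplitude`, `rise_s`, `decay_s`, `n`.
#' @export
waveform_kinetics <- function(eta, rate, fit_window = 2) {
  w <- eta$wave
  p <- which.max(w)
  amp <- w[p]
  t20 <- cross_time(eta$time[1:p], w[1:p], 0.2 * amp)
  t80 <- cross_time(eta$time[1:p], w[1:p], 0.8 * amp)
  last <- min(length(w), p + round(fit_window * rate))
  dk <- decay_tau(eta$time[p:last] - eta$time[p], w[p:last], amp)
  data.frame(amplitude = amp, rise_s = max(t80 - t20, 0), decay_s = dk$tau,
             n = eta$n)
}
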