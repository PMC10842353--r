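#' Detection parameters
#'
#' Defaults follow the field's standard procedure for 10-Hz bouton imaging: traces smoothed at 3 points,
#' events called at 3 SD above a 4-s trailing moving-average baseline, evoked
#' events time-locked within 0.3 s of a stimulus. The end threshold (1 SD) and
#' the merge gap (0.5 s) close out an event and prevent one noisy transient
#' from splitting in two.
#'
#' @param smooth_window Smoothing window, frames; odd, at most 5.
#' @param baseline_window Moving-baseline window, s.
#' @param threshold_sd Event onset threshold, in noise SDs above baseline.
#' @param evoked_window Time-lock window after a stimulus, s (closed on the
#'   left, open on the right).
#' @param merge_gap Events whose onsets are closer than this (s) merge.
#' @param end_threshold_sd Threshold (SDs above the frozen baseline) below
#'   which an event ends.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(smooth_window = 3, baseline_window = 4,
                             threshold_sd = 3, evoked_window = 0.3,
                             merge_gap = 0.5, end_threshold_sd = 1) {
  p <- list(smooth_window = as.integer(smooth_window),
            baseline_window = baseline_window, threshold_sd = threshold_sd,
            evoked_window = evoked_window, merge_gap = merge_gap,
            end_threshold_sd = end_threshold_sd)
  if (any(unlist(p) <= 0)) stop("all detection parameters must be positive")
  if (p$smooth_window %% 2 == 0) stop("smooth_window must be odd")
  if (p$smooth_window > 5) stop("smooth_window must be at most 5")
  class(p) <- "detection_params"
  p
}

#' Remove linear background drift, keeping the absolute level
#'
#' Fits a straight line by least squares to the trace's rolling
#' 10th-percentile series (consecutive 30-s blocks) and removes the slope
#' only: the fitted value at the first frame is retained, so the absolute
#' baseline level survives for downstream baseline quantification.
#'
#' @param f Numeric fluorescence vector.
#' @param rate Sampling rate, frames/s.
#' @param block_s Percentile block length, s.
#' @param prob Percentile used for the drift series.
#' @return Detrended vector, same length.
#' @export
subtract_background <- function(f, rate, block_s = 30, prob = 0.1) {
  n <- length(f)
  w <- round(block_s * rate)
  if (n < 100) stop("need at least 100 frames")
  if (n < w) stop("trace shorter than one percentile block")
  n_block <- n %/% w
  centers <- (seq_len(n_block) - 0.5) * w
  lows <- vapply(seq_len(n_block), function(b) {
    stats::quantile(f[((b - 1) * w + 1):(b * w)], prob, names = FALSE)
  }, numeric(1))
  slope <- if (n_block >= 2) stats::cov(centers, lows) / stats::var(centers) else 0
  f - slope * (seq_len(n) - 1)
}

#' Centered moving-average smoothing
#'
#' Window shrinks symmetrically at the edges; length is preserved. Window 1 is
#' the identity.
#'
#' @param f Numeric vector.
#' @param window Odd window size in frames.
#' @export
smooth_trace <- function(f, window = 3) {
  if (window %% 2 == 0) stop("smoothing window must be odd")
  if (window == 1) return(f)
  h <- (window - 1) / 2
  n <- length(f)
  cs <- cumsum(c(0, f))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Trailing moving-average baseline
#'
#' For frame `i`, the mean of the previous `window` seconds of trace,
#' excluding frame `i` itself; the window expands from the start of the trace
#' (frame 1 uses its own value). Length is preserved.
#'
#' @param f Numeric vector.
#' @param rate Sampling rate, frames/s.
#' @param window Baseline window, s.
#' @export
moving_baseline <- function(f, rate, window = 4) {
  w <- round(window * rate)
  if (w < 2) stop("baseline window must cover at least 2 frames")
  n <- length(f)
  if (n == 0) return(numeric(0))
  cs <- cumsum(c(0, f))
  i <- seq_len(n)
  lo <- pmax(i - w, 1)
  b <- (cs[i] - cs[lo]) / (i - lo)
  b[1] <- f[1]
  b
}

#' Robust noise SD of a detrended trace
#'
#' MAD (x 1.4826) of the residual `trace - moving_baseline(trace)` over
#' unmasked frames. The mask normally covers detected-event extents and 1 s
#' after each stimulus, so events do not inflate the noise estimate.
#'
#' @param f Detrended (unsmoothed) fluorescence vector.
#' @param rate Sampling rate, frames/s.
#' @param mask Logical vector, `TRUE` = excluded frame; `NULL` for none.
#' @param baseline_window Baseline window, s.
#' @return Scalar robust SD, same units as `f`.
#' @export
estimate_noise_sd <- function(f, rate, mask = NULL, baseline_window = 4) {
  r <- f - moving_baseline(f, rate, baseline_window)
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(f))
    r <- r[!mask]
  }
  if (length(r) < 50) stop("need at least 50 unmasked frames")
  stats::mad(r)
}

#' Frame-exclusion mask from events and stimuli
#'
#' @param n Number of frames.
#' @param time Frame start times, s.
#' @param events Detection table (may be `NULL`).
#' @param stim_times Stimulus times, s.
#' @param post_stim Seconds excluded after each stimulus.
#' @return Logical vector, `TRUE` = excluded.
#' @export
exclusion_mask <- function(n, time, events = NULL, stim_times = numeric(0),
                           post_stim = 1) {
  mask <- rep(FALSE, n)
  if (!is.null(events) && nrow(events)) {
    for (j in seq_len(nrow(events))) {
      mask[events$onset_idx[j]:events$end_idx[j]] <- TRUE
    }
  }
  for (s in stim_times) {
    mask[time >= s & time < s + post_stim] <- TRUE
  }
  mask
}

#' Threshold-crossing event detection with a frozen baseline
#'
#' Scans the smoothed, detrended trace against its trailing moving-average
#' baseline. An event starts at the first frame where
#' `trace - baseline > threshold_sd * sigma`; while the event lasts, the
#' baseline is frozen at its onset value so the event cannot absorb itself
#' into the baseline; the event ends at the last frame before
#' `trace - frozen < end_threshold_sd * sigma`. Events with onsets closer
#' than `merge_gap` merge (earliest onset, largest peak). An event is
#' `evoked` if its onset lies in `[t_stim, t_stim + evoked_window)` for some
#' stimulus, else `spontaneous`.
#'
#' @param s Smoothed, detrended fluorescence vector.
#' @param rate Sampling rate, frames/s.
#' @param sigma Noise SD (from [estimate_noise_sd()] on the unsmoothed
#'   detrended trace). Must be positive.
#' @param params [detection_params()].
#' @param time Frame start times, s (default `0, 1/rate, ...`).
#' @param stim_times Stimulus times, s.
#' @return `data.frame` with one row per event: `onset_idx`, `peak_idx`,
#'   `end_idx` (1-based frame indices), `onset_s`, `peak_s`, `end_s`,
#'   `class`, `stim_index` (`NA` for spontaneous), `frozen_baseline`,
#'   `peak_value`, `truncated` (event still above the end threshold at the
#'   trace end).
#' @export
detect_events <- function(s, rate, sigma, params = detection_params(),
                          time = NULL, stim_times = numeric(0)) {
  n <- length(s)
  if (is.null(time)) time <- (seq_len(n) - 1) / rate
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) ||
      sigma <= 0) {
    stop("degenerate trace: noise SD is zero or undefined")
  }
  b <- moving_baseline(s, rate, params$baseline_window)
  th_on <- params$threshold_sd * sigma
  th_off <- params$end_threshold_sd * sigma

  above <- which(s - b > th_on)
  onset <- integer(0); endf <- integer(0); peak <- integer(0)
  frozen <- numeric(0); trunc <- logical(0)
  i <- 1L
  while (length(above)) {
    above <- above[above >= i]
    if (!length(above)) break
    o <- above[1]
    fb <- b[o]
    j <- o + 1L
    while (j <= n && s[j] - fb >= th_off) j <- j + 1L
    e <- min(j - 1L, n)
    p <- o + which.max(s[o:e]) - 1L
    onset <- c(onset, o); endf <- c(endf, e); peak <- c(peak, p)
    frozen <- c(frozen, fb); trunc <- c(trunc, j > n)
    i <- j
  }

  if (length(onset)) {
    # merge events whose onsets are closer than merge_gap
    keep_o <- onset[1]; keep_e <- endf[1]; keep_p <- peak[1]
    keep_f <- frozen[1]; keep_t <- trunc[1]
    out_o <- integer(0); out_e <- integer(0); out_p <- integer(0)
    out_f <- numeric(0); out_t <- logical(0)
    if (length(onset) > 1) {
      for (k in 2:length(onset)) {
        if (time[onset[k]] - time[keep_o] < params$merge_gap) {
          if (s[peak[k]] > s[keep_p]) keep_p <- peak[k]
          keep_e <- max(keep_e, endf[k])
          keep_t <- keep_t || trunc[k]
        } else {
          out_o <- c(out_o, keep_o); out_e <- c(out_e, keep_e)
          out_p <- c(out_p, keep_p); out_f <- c(out_f, keep_f)
          out_t <- c(out_t, keep_t)
          keep_o <- onset[k]; keep_e <- endf[k]; keep_p <- peak[k]
          keep_f <- frozen[k]; keep_t <- trunc[k]
        }
      }
    }
    out_o <- c(out_o, keep_o); out_e <- c(out_e, keep_e)
    out_p <- c(out_p, keep_p); out_f <- c(out_f, keep_f)
    out_t <- c(out_t, keep_t)
    onset <- out_o; endf <- out_e; peak <- out_p; frozen <- out_f
    trunc <- out_t
  }

  cls <- rep("spontaneous", length(onset))
  stim_index <- rep(NA_integer_, length(onset))
  if (length(stim_times) && length(onset)) {
    for (k in seq_along(onset)) {
      dt <- time[onset[k]] - stim_times
      hit <- which(dt >= 0 & dt < params$evoked_window)
      if (length(hit)) {
        cls[k] <- "evoked"
        stim_index[k] <- hit[length(hit)]
      }
    }
  }

  data.frame(
    onset_idx = onset, peak_idx = peak, end_idx = endf,
    onset_s = time[onset], peak_s = time[peak], end_s = time[endf],
    class = cls, stim_index = stim_index,
    frozen_baseline = frozen, peak_value = s[peak], truncated = trunc
  )
}

#' Full single-trace detection pipeline
#'
#' Runs background subtraction, smoothing, a two-pass noise estimate (events
#' detected with a provisional SD are masked before the final estimate), final
#' detection and per-event kinetics.
#'
#' @param f Raw fluorescence vector (one ROI).
#' @param rate Sampling rate, frames/s.
#' @param params [detection_params()].
#' @param time Frame start times, s.
#' @param stim_times Stimulus times, s.
#' @param kinetics Compute per-event kinetics (default `TRUE`).
#' @return List: `events` (detection table joined with kinetics), `sigma`
#'   (final noise SD, F units), `detrended`, `smoothed`, `baseline` vectors,
#'   and `mask` (final exclusion mask).
#' @export
detect_trace <- function(f, rate, params = detection_params(), time = NULL,
                         stim_times = numeric(0), kinetics = TRUE) {
  n <- length(f)
  if (is.null(time)) time <- (seq_len(n) - 1) / rate
  d <- subtract_background(f, rate)
  s <- smooth_trace(d, params$smooth_window)

  mask0 <- exclusion_mask(n, time, NULL, stim_times)
  sigma0 <- estimate_noise_sd(d, rate, mask0, params$baseline_window)
  if (sigma0 <= 0) stop("degenerate trace: provisional noise SD is zero")
  ev0 <- detect_events(s, rate, sigma0, params, time, stim_times)
  mask <- exclusion_mask(n, time, ev0, stim_times)
  sigma <- tryCatch(
    estimate_noise_sd(d, rate, mask, params$baseline_window),
    error = function(e) sigma0 # nearly everything masked: keep provisional
  )
  if (sigma <= 0) sigma <- sigma0
  ev <- detect_events(s, rate, sigma, params, time, stim_times)
  if (kinetics) {
    ev <- cbind(ev, event_kinetics(s, rate, ev, time = time, amp_trace = d))
  }
  list(events = ev, sigma = sigma, detrended = d, smoothed = s,
       baseline = moving_baseline(s, rate, params$baseline_window),
       mask = exclusion_mask(n, time, ev, stim_times))
}
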