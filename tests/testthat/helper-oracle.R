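# Independent, deliberately naive frame-by-frame reference implementation of
# the detection rules, used as the oracle for equivalence tests. Computes the
# trailing baseline with mean() at every frame and walks the trace with an
# explicit state machine; shares no code with the package's scanner.
naive_detect <- function(s, rate, sigma, params = detection_params(),
                         time = NULL, stim_times = numeric(0)) {
  n <- length(s)
  if (is.null(time)) time <- (seq_len(n) - 1) / rate
  w <- round(params$baseline_window * rate)
  th_on <- params$threshold_sd * sigma
  th_off <- params$end_threshold_sd * sigma
  base_at <- function(i) if (i == 1) s[1] else mean(s[max(1, i - w):(i - 1)])

  onset <- integer(0); endf <- integer(0); frozen <- numeric(0)
  trunc <- logical(0)
  in_ev <- FALSE; o <- NA_integer_; fb <- NA_real_
  i <- 1L
  while (i <= n) {
    if (in_ev) {
      if (s[i] - fb < th_off) {
        onset <- c(onset, o); endf <- c(endf, i - 1L)
        frozen <- c(frozen, fb); trunc <- c(trunc, FALSE)
        in_ev <- FALSE
        # frame i may itself start a new event; fall through
      } else {
        i <- i + 1L
        next
      }
    }
    b <- base_at(i)
    if (s[i] - b > th_on) {
      in_ev <- TRUE; o <- i; fb <- b
    }
    i <- i + 1L
  }
  if (in_ev) {
    onset <- c(onset, o); endf <- c(endf, n)
    frozen <- c(frozen, fb); trunc <- c(trunc, TRUE)
  }

  # merge pass: onset within merge_gap of the group's earliest onset
  if (length(onset) > 1) {
    g_o <- onset[1]; g_e <- endf[1]; g_f <- frozen[1]; g_t <- trunc[1]
    m_o <- integer(0); m_e <- integer(0); m_f <- numeric(0); m_t <- logical(0)
    for (k in 2:length(onset)) {
      if (time[onset[k]] - time[g_o] < params$merge_gap) {
        g_e <- max(g_e, endf[k]); g_t <- g_t || trunc[k]
      } else {
        m_o <- c(m_o, g_o); m_e <- c(m_e, g_e); m_f <- c(m_f, g_f)
        m_t <- c(m_t, g_t)
        g_o <- onset[k]; g_e <- endf[k]; g_f <- frozen[k]; g_t <- trunc[k]
      }
    }
    m_o <- c(m_o, g_o); m_e <- c(m_e, g_e); m_f <- c(m_f, g_f)
    m_t <- c(m_t, g_t)
    onset <- m_o; endf <- m_e; frozen <- m_f; trunc <- m_t
  }

  peak <- vapply(seq_along(onset), function(k) {
    rng <- onset[k]:endf[k]
    rng[which.max(s[rng])]
  }, integer(1))
  cls <- rep("spontaneous", length(onset))
  stim_index <- rep(NA_integer_, length(onset))
  for (k in seq_along(onset)) {
    dt <- time[onset[k]] - stim_times
    hit <- which(dt >= 0 & dt < params$evoked_window)
    if (length(hit)) {
      cls[k] <- "evoked"
      stim_index[k] <- hit[length(hit)]
    }
  }
  data.frame(onset_idx = onset, peak_idx = peak, end_idx = endf,
             class = cls, stim_index = stim_index,
             frozen_baseline = frozen, truncated = trunc)
}

# Plant unit-peak kernels of amplitude `amp` at `times` on a noise trace.
plant_events <- function(n, rate, times, amp, tau_rise = 0.05,
                         tau_decay = 0.5, noise_sd = 1, level = 0,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tfr <- (seq_len(n) - 1) / rate
  s <- rep(level, n) + stats::rnorm(n, 0, noise_sd)
  for (j in seq_along(times)) {
    a <- if (length(amp) == 1) amp else amp[j]
    idx <- which(tfr >= times[j])
    s[idx] <- s[idx] + a * transient_kernel(tfr[idx] - times[j],
                                           tau_rise, tau_decay)
  }
  list(s = s, time = tfr)
}
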