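#' Simulate one bouton's fluorescence trace
#'
#' Forward model of the three-class bouton signal. With unbleached fractions
#' `u = (uE, uS, uB)` held at their epoch-start values,
#' \deqn{F(t) = F0 (1 + u_E \sum_e A_e k_e(t) + u_S \sum_s A_s k_s(t)
#'              + u_B b(t)) + \epsilon(t)}
#' where `k` is the unit-peak difference-of-exponentials kernel, evoked events
#' occur at stimulus times with probability `p_evoked`, spontaneous events are
#' a homogeneous Poisson process at `lambda_spont`, `b(t)` is the shot-noise
#' superposition of micro-transients (rate `shot_rate`, amplitude `shot_amp`)
#' and `eps` is Gaussian read noise. High-K+ epochs add a saturating plateau
#' driven by all three classes. Frames are produced for imaging epochs only;
#' bleach and dark epochs advance the photobleaching state analytically.
#'
#' Randomness is consumed from per-epoch, per-class substreams derived from
#' `config$seed`, so two sessions whose schedules share epoch structure draw
#' identical events in their common epochs (matched-control pairing).
#'
#' @param config A [bouton_config()].
#' @param schedule A [stim_schedule()].
#' @param u0 Initial unbleached fractions (default all 1).
#' @return A list with elements
#'   \item{trace}{`fluor_trace`: fluorescence vector `F`, frame times `time`,
#'     epoch labels `epoch`, sampling `rate`;}
#'   \item{truth}{ground truth: `events` (time, class, amplitude in dF/F0,
#'     fluorescent amplitude after bleach scaling), per-epoch unbleached
#'     fractions `u`, and per-epoch true baseline level (F units).}
#' @export
simulate_trace <- function(config, schedule, u0 = c(E = 1, S = 1, B = 1)) {
  stopifnot(inherits(config, "bouton_config"), inherits(schedule, "stim_schedule"))
  validate_config(config)
  rate <- config$sampling_rate
  ep <- schedule$epochs
  uu <- unbleached_timecourse(schedule, config, u0 = u0)

  # per-epoch substreams: evoked, spontaneous, shot, read noise
  set.seed(config$seed)
  sub <- matrix(sample.int(.Machine$integer.max, nrow(ep) * 4L), ncol = 4L)

  sdlog_e <- sqrt(log(1 + config$cv_evoked^2))
  sdlog_s <- sqrt(log(1 + config$cv_spont^2))
  k_shot <- kernel_frames(config$tau_rise_shot, config$tau_decay, rate)
  warm <- length(k_shot)

  frames_list <- list()
  events_list <- list()
  base_list <- list()

  for (i in seq_len(nrow(ep))) {
    u <- as.numeric(uu[i, c("uE", "uS", "uB")])
    t0 <- ep$start[i]
    t1 <- ep$end[i]

    # evoked events exist in any stimulated epoch (they matter for bleaching
    # even when unrecorded, but only recorded epochs need realizations)
    ev <- NULL
    if (ep$stimulated[i] && ep$illumination[i] == "imaging") {
      st <- schedule$stim_times
      st <- st[st >= t0 & st < t1]
      if (length(st)) {
        set.seed(sub[i, 1])
        hit <- stats::rbinom(length(st), 1, config$p_evoked) == 1
        amp <- stats::rlnorm(length(st),
                             log(config$A_evoked * config$ca_scale), sdlog_e)
        if (any(hit)) {
          ev <- data.frame(time = st[hit], class = "evoked",
                           amplitude = amp[hit], stim_time = st[hit])
        }
      }
    }
    sp <- NULL
    if (ep$illumination[i] == "imaging" && config$lambda_spont > 0) {
      set.seed(sub[i, 2])
      n_sp <- stats::rpois(1, config$lambda_spont / 60 * (t1 - t0))
      if (n_sp > 0) {
        tt <- sort(stats::runif(n_sp, t0, t1))
        amp <- stats::rlnorm(n_sp, log(config$A_spont), sdlog_s)
        sp <- data.frame(time = tt, class = "spontaneous", amplitude = amp,
                         stim_time = NA_real_)
      }
    }

    if (ep$illumination[i] != "imaging") next
    n <- round((t1 - t0) * rate)
    tfr <- t0 + (seq_len(n) - 1) / rate
    sig <- numeric(n)

    if (!is.null(ev)) {
      for (j in seq_len(nrow(ev))) {
        sig <- add_kernel(sig, tfr, ev$time[j], u[1] * ev$amplitude[j],
                          config$tau_rise_evoked, config$tau_decay)
      }
    }
    if (!is.null(sp)) {
      for (j in seq_len(nrow(sp))) {
        sig <- add_kernel(sig, tfr, sp$time[j], u[2] * sp$amplitude[j],
                          config$tau_rise_spont, config$tau_decay_spont)
      }
    }

    # shot-noise baseline with a warm-up lead-in so the process is stationary
    # from the first frame of the epoch
    b_mu <- 0
    if (config$shot_rate > 0 && config$shot_amp > 0) {
      set.seed(sub[i, 3])
      counts <- stats::rpois(n + warm, config$shot_rate * config$ca_scale / rate)
      b <- conv_causal(counts * config$shot_amp, k_shot)[warm + seq_len(n)]
      sig <- sig + u[3] * b
      b_mu <- u[3] * baseline_occupancy(config)
    }
    if (ep$highk[i]) {
      plateau <- u[1] * config$A_evoked * config$ca_scale +
        u[2] * config$A_spont +
        u[3] * baseline_occupancy(config) * config$highk_boost
      sig <- sig + plateau
      b_mu <- b_mu + plateau
    }

    f <- config$F0 * (1 + sig)
    if (config$sigma_noise > 0) {
      set.seed(sub[i, 4])
      f <- f + stats::rnorm(n, 0, config$sigma_noise)
    }
    frames_list[[length(frames_list) + 1L]] <-
      list(f = f, time = tfr, epoch = rep(ep$label[i], n))
    if (!is.null(ev)) events_list[[length(events_list) + 1L]] <- ev
    if (!is.null(sp)) events_list[[length(events_list) + 1L]] <- sp
    base_list[[length(base_list) + 1L]] <-
      data.frame(epoch = ep$label[i], level = config$F0 * (1 + b_mu))
  }

  events <- if (length(events_list)) {
    ev <- do.call(rbind, events_list)
    ev <- ev[order(ev$time), , drop = FALSE]
    rownames(ev) <- NULL
    u_of <- function(tt) {
      idx <- findInterval(tt, uu$start)
      idx[idx < 1] <- 1
      idx
    }
    ev$amplitude_fluor <- ev$amplitude *
      ifelse(ev$class == "evoked", uu$uE[u_of(ev$time)], uu$uS[u_of(ev$time)])
    ev
  } else {
    data.frame(time = numeric(0), class = character(0),
               amplitude = numeric(0), stim_time = numeric(0),
               amplitude_fluor = numeric(0))
  }

  trace <- structure(list(
    F = unlist(lapply(frames_list, `[[`, "f")),
    time = unlist(lapply(frames_list, `[[`, "time")),
    epoch = unlist(lapply(frames_list, `[[`, "epoch")),
    rate = rate
  ), class = "fluor_trace")

  list(trace = trace,
       truth = list(events = events, u = uu,
                    baseline = do.call(rbind, base_list)))
}

#' Add a scaled unit-peak kernel to a signal vector (in place value)
#' @noRd
add_kernel <- function(sig, tfr, onset, amp, tau_rise, tau_decay) {
  if (amp == 0) return(sig)
  support <- kernel_peak_time(tau_rise, tau_decay) + 8 * tau_decay
  idx <- which(tfr >= onset & tfr <= onset + support)
  if (length(idx)) {
    sig[idx] <- sig[idx] +
      amp * transient_kernel(tfr[idx] - onset, tau_rise, tau_decay)
  }
  sig
}

#' Causal discrete convolution, output aligned with input
#' @noRd
conv_causal <- function(x, k) {
  L <- length(k)
  y <- stats::filter(c(rep(0, L - 1), x), k, method = "convolution", sides = 1)
  as.numeric(y[(L - 1) + seq_along(x)])
}

#' Simulate a cohort of boutons sharing one schedule
#'
#' Simulates `n_roi` independent boutons. A fraction `silent_fraction` of them
#' is spontaneously silent (`lambda_spont = 0`), matching the observation that
#' most detected synapses show no spontaneous transients; active boutons keep
#' the configured `lambda_spont`. ROIs are assigned round-robin to
#' `n_coverslip` coverslips (the replicate unit for cohort statistics).
#'
#' @param config A [bouton_config()].
#' @param schedule A [stim_schedule()].
#' @param n_roi Number of boutons.
#' @param silent_fraction Fraction of boutons with no spontaneous events.
#' @param n_coverslip Number of coverslips.
#' @param seed Master seed (default `config$seed`); per-ROI seeds and the
#'   silent assignment derive from it.
#' @param u0 Initial unbleached fractions.
#' @return List with `traces` (list of `fluor_trace`), `truths`, and `rois`
#'   (`data.frame`: roi, coverslip, silent, seed).
#' @export
simulate_cohort <- function(config, schedule, n_roi, silent_fraction = 0,
                            n_coverslip = 1, seed = config$seed,
                            u0 = c(E = 1, S = 1, B = 1)) {
  stopifnot(n_roi >= 1, silent_fraction >= 0, silent_fraction <= 1)
  set.seed(seed)
  roi_seeds <- sample.int(.Machine$integer.max, n_roi)
  n_silent <- round(silent_fraction * n_roi)
  silent <- rep(FALSE, n_roi)
  if (n_silent > 0) silent[sample.int(n_roi, n_silent)] <- TRUE
  rois <- data.frame(
    roi = seq_len(n_roi),
    coverslip = rep_len(seq_len(n_coverslip), n_roi),
    silent = silent,
    seed = roi_seeds
  )
  sims <- lapply(seq_len(n_roi), function(i) {
    cfg <- unclass(config)
    cfg$seed <- roi_seeds[i]
    if (silent[i]) cfg$lambda_spont <- 0
    class(cfg) <- "bouton_config"
    simulate_trace(cfg, schedule, u0 = u0)
  })
  list(traces = lapply(sims, `[[`, "trace"),
       truths = lapply(sims, `[[`, "truth"),
       rois = rois)
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> %d frames @ %g Hz, epochs: %s\n",
              length(x$F), x$rate, paste(unique(x$epoch), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.fluor_trace <- function(x, ...) {
  data.frame(time = x$time, F = x$F, epoch = x$epoch)
}

#' Extract the sub-trace of one epoch
#'
#' @param trace A `fluor_trace`.
#' @param label Epoch label (or vector of labels).
#' @return A `fluor_trace` restricted to the matching frames.
#' @export
trace_epoch <- function(trace, label) {
  keep <- trace$epoch %in% label
  if (!any(keep)) stop("no frames in epoch(s) ", paste(label, collapse = ", "))
  structure(list(F = trace$F[keep], time = trace$time[keep],
                 epoch = trace$epoch[keep], rate = trace$rate),
            class = "fluor_trace")
}
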