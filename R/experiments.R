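#' Planted-effect treatment experiment on spontaneous frequency
#'
#' Simulates a cohort of spontaneously active boutons before and after a
#' treatment that scales the spontaneous event rate (configs identical
#' otherwise), runs the detection pipeline on both epochs, and reports the
#' detected after-treatment frequency as a percentage of the before
#' frequency under the requested normalization convention:
#' `gcamp` — coverslip-aggregated (mean after frequency over the coverslip
#' mean before frequency); `iglusnfr` — synapse-by-synapse ratios averaged
#' across ROIs (boutons with no before events are excluded, as their
#' normalization is undefined).
#'
#' @param config Generative preset, e.g. [bouton_config()] or
#'   [iglusnfr_config()].
#' @param treatment Passed to [apply_treatment()] (`"ryanodine"` scales the
#'   spontaneous rate; `"vgcc"` also scales the shot rate).
#' @param block Blocked fraction in `[0,1]`.
#' @param n_roi Number of boutons.
#' @param minutes Epoch length, minutes (one before and one after epoch).
#' @param mode Normalization convention.
#' @param n_coverslip Coverslips for the gcamp aggregation.
#' @param seed Master seed.
#' @param params [detection_params()].
#' @return List: `value` (percentage), `n` (ROI count),
#'   `n_events_before`, `n_events_after`, `n_excluded`.
#' @export
spont_treatment_experiment <- function(config, treatment = "ryanodine",
                                       block, n_roi = 300, minutes = 10,
                                       mode = c("gcamp", "iglusnfr"),
                                       n_coverslip = 10, seed = 1,
                                       params = detection_params()) {
  mode <- match.arg(mode)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2)
  sch <- schedule_spont(minutes * 60)
  cfg_after <- apply_treatment(config, treatment, block)

  measure <- function(cfg, s) {
    cohort <- simulate_cohort(cfg, sch, n_roi, silent_fraction = 0,
                              n_coverslip = n_coverslip, seed = s)
    rows <- lapply(seq_len(n_roi), function(i) {
      tr <- cohort$traces[[i]]
      det <- detect_trace(tr$F, tr$rate, params, kinetics = FALSE)
      data.frame(roi = i, coverslip = cohort$rois$coverslip[i],
                 spont_frequency = nrow(det$events) / minutes)
    })
    do.call(rbind, rows)
  }
  before <- measure(config, seeds[1])
  after <- measure(cfg_after, seeds[2])
  cmp <- compare_epochs(before, after, mode, metrics = "spont_frequency")
  list(value = 100 * unname(cmp$mean["spont_frequency"]),
       n = n_roi,
       n_events_before = sum(before$spont_frequency) * minutes,
       n_events_after = sum(after$spont_frequency) * minutes,
       n_excluded = unname(cmp$n_excluded["spont_frequency"]))
}

#' Planted-effect blockade experiment on evoked events
#'
#' Simulates boutons receiving `n_stim` stimuli before and after a blockade
#' that scales the per-stimulus response probability, runs evoked detection,
#' and reports the percentage decrease in detected evoked events.
#'
#' @param config Generative preset.
#' @param block Blocked fraction applied to `p_evoked` (via the `vgcc`
#'   treatment).
#' @param n_roi Number of boutons.
#' @param n_stim Stimuli per bouton (10-s intervals).
#' @param seed Master seed.
#' @param params [detection_params()].
#' @return List: `value` (percentage decrease), `n` (ROI count),
#'   `events_before`, `events_after`.
#' @export
evoked_blockade_experiment <- function(config, block, n_roi = 100,
                                       n_stim = 60, seed = 1,
                                       params = detection_params()) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2)
  sch <- schedule_evoked(n_stim)
  cfg_after <- apply_treatment(config, "vgcc", block)

  count_evoked <- function(cfg, s) {
    cohort <- simulate_cohort(cfg, sch, n_roi, seed = s)
    sum(vapply(cohort$traces, function(tr) {
      det <- detect_trace(tr$F, tr$rate, params, time = tr$time,
                          stim_times = sch$stim_times, kinetics = FALSE)
      sum(det$events$class == "evoked")
    }, numeric(1)))
  }
  nb <- count_evoked(config, seeds[1])
  na <- count_evoked(cfg_after, seeds[2])
  list(value = 100 * (1 - na / nb), n = n_roi,
       events_before = nb, events_after = na)
}

#' Use-dependent photobleaching experiment (Table-style matrix)
#'
#' Runs matched sessions under the three bleach protocols (at rest, with
#' stimulation, with high K+) plus the no-bleach control. Control sessions
#' share the bleach sessions' seeds, so each protocol's ratios are compared
#' against a control with identical event and noise draws and the
#' susceptibility calls isolate the bleaching effect.
#'
#' @param n_sessions Sessions per arm.
#' @param n_roi Boutons per session.
#' @param config Generative preset.
#' @param seed Master seed.
#' @param margin Susceptibility margin (ratio scale).
#' @param t_bleach Bleach duration, s.
#' @return List: `matrix` (from [bleach_susceptibility()]), `arms` (pooled
#'   before/after metrics per arm).
#' @export
bleach_matrix_experiment <- function(n_sessions = 200, n_roi = 2,
                                     config = bouton_config(), seed = 1,
                                     margin = 0.10, t_bleach = 1800) {
  set.seed(seed)
  session_seeds <- sample.int(.Machine$integer.max, n_sessions)
  run_arm <- function(protocol) {
    sch <- schedule_bleach_session(protocol, t_bleach = t_bleach)
    traces <- list()
    for (s in seq_len(n_sessions)) {
      co <- simulate_cohort(config, sch, n_roi, silent_fraction = 0,
                            seed = session_seeds[s])
      traces <- c(traces, co$traces)
    }
    cohort <- list(traces = traces)
    list(before = pooled_epoch_metrics(cohort, sch, "before_spont",
                                       "before_evoked"),
         after = pooled_epoch_metrics(cohort, sch, "after_spont",
                                      "after_evoked"))
  }
  arms <- lapply(c(control = "control", rest = "rest", stim = "stim",
                   highk = "highk"), run_arm)
  list(matrix = bleach_susceptibility(arms[c("rest", "stim", "highk")],
                                      arms$control, margin = margin),
       arms = arms)
}

#' Fluorescence-recovery experiment after maximal photobleaching
#'
#' Bleaches with stimulation for `t_bleach` seconds, waits in the dark for
#' each recovery duration, then remeasures. Reports measured recovery
#' fractions alongside the single-rate exchange prediction
#' `u(t) = 1 - (1 - u0) exp(-k_exchange t)` evaluated at the measurement
#' epoch start (with `u0` the closed-form post-bleach evoked-pool fraction).
#'
#' @param durations_min Recovery durations, minutes, strictly increasing.
#' @param n_sessions Sessions per duration.
#' @param n_roi Boutons per session.
#' @param config Generative preset.
#' @param seed Master seed.
#' @param t_bleach Bleach duration, s.
#' @return List: `curve` (from [recovery_curve()] with a `predicted_u`
#'   column for the evoked pool), `u0` (post-bleach evoked fraction).
#' @export
recovery_experiment <- function(durations_min = c(0, 60, 180, 300),
                                n_sessions = 40, n_roi = 2,
                                config = bouton_config(), seed = 1,
                                t_bleach = 1800) {
  set.seed(seed)
  session_seeds <- sample.int(.Machine$integer.max, n_sessions)
  sessions <- lapply(durations_min, function(d) {
    sch <- schedule_bleach_session("stim", t_bleach = t_bleach,
                                   t_recovery = d * 60)
    traces <- list()
    for (s in seq_len(n_sessions)) {
      co <- simulate_cohort(config, sch, n_roi, silent_fraction = 0,
                            seed = session_seeds[s])
      traces <- c(traces, co$traces)
    }
    cohort <- list(traces = traces)
    list(before = pooled_epoch_metrics(cohort, sch, "before_spont",
                                       "before_evoked"),
         after = pooled_epoch_metrics(cohort, sch, "after_spont",
                                      "after_evoked"),
         schedule = sch)
  })
  curve <- recovery_curve(sessions, durations_min)
  # closed-form prediction for the evoked pool at the evoked-measurement epoch
  sch0 <- sessions[[1]]$schedule
  duty_e <- duty_cycles(list(stimulated = TRUE, highk = FALSE), config)["E"]
  kx <- config$k_exchange / 60
  kb <- config$k_bleach * config$bleach_illum_duty * duty_e
  u_inf <- kx / (kx + kb)
  u0 <- u_inf + (1 - u_inf) * exp(-(kx + kb) * t_bleach)
  ep <- sch0$epochs
  lag_s <- ep$start[ep$label == "after_evoked"] - ep$end[ep$label == "bleach"]
  curve$predicted_u <- 1 - (1 - u0) * exp(-kx * (durations_min * 60 + lag_s))
  list(curve = curve, u0 = u0)
}
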