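#' Exact update of unbleached pool fractions
#'
#' Use-dependent photobleaching with reservoir exchange. Each sensor pool `p`
#' obeys `du_p/dt = -k_bleach * duty_p * u_p + k_exchange * (1 - u_p)`: only
#' sensors that are fluorescent (fraction of time `duty_p`) can be bleached,
#' while a slow exchange with an infinite unbleached reservoir pulls every pool
#' back toward 1. The update is the exact solution over `dt` (no Euler drift),
#' so fractions stay in `[0,1]` for any step size.
#'
#' @param u Numeric vector of unbleached fractions in `[0,1]` (one per pool).
#' @param duty Fluorescent duty cycle per pool, same length as `u`, in `[0,1]`.
#' @param dt Time step, s; must be positive.
#' @param config A [bouton_config()] supplying `k_bleach` (per s) and
#'   `k_exchange` (per min).
#' @param bleaching Logical; if `FALSE` (illumination off) only exchange acts.
#' @return Updated fractions, same length as `u`.
#' @export
apply_bleach_step <- function(u, duty, dt, config, bleaching = TRUE) {
  if (length(duty) != length(u)) stop("u and duty must have equal length")
  if (any(u < 0 | u > 1)) stop("u must lie in [0,1]")
  if (any(duty < 0 | duty > 1)) stop("duty must lie in [0,1]")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be positive")
  kb <- if (bleaching) config$k_bleach * duty else rep(0, length(u))
  kx <- config$k_exchange / 60
  r <- kb + kx
  u_inf <- ifelse(r > 0, kx / r, u) # r = 0: no dynamics at all
  u_inf + (u - u_inf) * exp(-r * dt)
}

#' Fluorescent duty cycle of the three pools in an epoch
#'
#' Maps epoch conditions to the fraction of time each pool's sensors are
#' fluorescent, which is what exposes them to use-dependent photobleaching:
#' \itemize{
#'   \item evoked pool: per-stimulus transient occupancy,
#'     `p_evoked * kernel_area / stim_interval`, and 0 without stimulation;
#'   \item spontaneous pool: `lambda_spont * kernel_area` (tiny — the basis of
#'     the spontaneous class's resistance to photobleaching);
#'   \item baseline pool: resting shot-noise occupancy
#'     `shot_rate * shot_amp * kernel_area`, scaled by `ca_scale`;
#'   \item high-K+ epochs saturate all three pools: duty `(1, 1, 1)`.
#' }
#'
#' @param epoch One row of a schedule's `epochs` data.frame (or a list with
#'   `stimulated` and `highk`).
#' @param config A [bouton_config()].
#' @param stim_interval Inter-stimulus interval, s, for stimulated epochs.
#' @return Named numeric triple `(E, S, B)` in `[0,1]`.
#' @export
duty_cycles <- function(epoch, config, stim_interval = 10) {
  if (isTRUE(epoch$highk)) {
    return(c(E = 1, S = 1, B = 1))
  }
  duty_e <- if (isTRUE(epoch$stimulated)) {
    config$p_evoked *
      kernel_area(config$tau_rise_evoked, config$tau_decay) / stim_interval
  } else {
    0
  }
  duty_s <- (config$lambda_spont / 60) *
    kernel_area(config$tau_rise_spont, config$tau_decay_spont)
  duty_b <- baseline_occupancy(config)
  pmin(c(E = duty_e, S = duty_s, B = duty_b), 1)
}

#' Unbleached fractions over a full session
#'
#' Walks the schedule epoch by epoch, applying the exact bleach/exchange
#' update with that epoch's duty cycles. Bleaching acts only during epochs
#' with `bleach` illumination (scaled by `bleach_illum_duty`); exchange acts
#' in every epoch.
#'
#' @param schedule A [stim_schedule()].
#' @param config A [bouton_config()].
#' @param u0 Initial fractions (default all 1).
#' @return `data.frame` with one row per epoch: label, start, end, and the
#'   unbleached fractions of the three pools at the epoch start
#'   (`uE`, `uS`, `uB`) and end (`uE_end`, ...).
#' @export
unbleached_timecourse <- function(schedule, config, u0 = c(E = 1, S = 1, B = 1)) {
  ep <- schedule$epochs
  n <- nrow(ep)
  out <- data.frame(label = ep$label, start = ep$start, end = ep$end,
                    uE = NA_real_, uS = NA_real_, uB = NA_real_,
                    uE_end = NA_real_, uS_end = NA_real_, uB_end = NA_real_)
  u <- u0
  stim_iv <- infer_stim_interval(schedule)
  for (i in seq_len(n)) {
    out[i, c("uE", "uS", "uB")] <- u
    duty <- duty_cycles(ep[i, ], config, stim_interval = stim_iv)
    bleaching <- ep$illumination[i] == "bleach"
    if (bleaching) {
      duty <- duty * config$bleach_illum_duty
    }
    u <- apply_bleach_step(u, duty, ep$end[i] - ep$start[i], config,
                           bleaching = bleaching)
    out[i, c("uE_end", "uS_end", "uB_end")] <- u
  }
  out
}

infer_stim_interval <- function(schedule) {
  st <- schedule$stim_times
  if (length(st) >= 2) stats::median(diff(st)) else 10
}
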