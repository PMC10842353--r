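#' Per-synapse summary metrics
#'
#' Collapses a detection table for one ROI into the metrics reported per
#' synapse: likelihood of an evoked response per stimulus, spontaneous
#' frequency (events/min), activity flag, and mean amplitudes per class.
#'
#' @param events Detection table with kinetics (from [detect_trace()]).
#' @param stim_times Stimulus times delivered during the recording.
#' @param duration_min Analyzed recording length, minutes.
#' @return One-row `data.frame`: `evoked_likelihood` (`NA` when no stimuli
#'   were delivered — undefined, not zero), `spont_frequency`,
#'   `n_evoked`, `n_spont`, `active`, `amp_evoked_df`, `amp_evoked_dff`,
#'   `amp_spont_df`, `amp_spont_dff`.
#' @export
summarize_synapse <- function(events, stim_times, duration_min) {
  stopifnot(duration_min > 0)
  ev <- events[events$class == "evoked", , drop = FALSE]
  sp <- events[events$class == "spontaneous", , drop = FALSE]
  likelihood <- if (length(stim_times) == 0) {
    NA_real_
  } else {
    length(unique(ev$stim_index[!is.na(ev$stim_index)])) / length(stim_times)
  }
  spont_freq <- nrow(sp) / duration_min
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  data.frame(
    evoked_likelihood = likelihood,
    spont_frequency = spont_freq,
    n_evoked = nrow(ev), n_spont = nrow(sp),
    active = spont_freq > 0,
    amp_evoked_df = mean_or_na(ev$amplitude_df),
    amp_evoked_dff = mean_or_na(ev$amplitude_dff),
    amp_spont_df = mean_or_na(sp$amplitude_df),
    amp_spont_dff = mean_or_na(sp$amplitude_dff)
  )
}

#' Run detection over every imaging epoch of a session trace
#'
#' Each imaging epoch is detected independently (its own background fit,
#' noise estimate and moving baseline), with the stimuli that fall inside it.
#'
#' @param trace A `fluor_trace` from [simulate_trace()] (or built from data).
#' @param schedule The session [stim_schedule()].
#' @param params [detection_params()].
#' @param epochs Epoch labels to analyze (default: all imaging epochs).
#' @param kinetics Compute per-event kinetics.
#' @return List: `events` (all epochs, with an `epoch` column), `sigma`
#'   (named per epoch), `summaries` (one row per epoch from
#'   [summarize_synapse()], with epoch, duration and stimulus count).
#' @export
detect_session <- function(trace, schedule, params = detection_params(),
                           epochs = NULL, kinetics = TRUE) {
  ep <- schedule$epochs
  labels <- ep$label[ep$illumination == "imaging"]
  if (!is.null(epochs)) labels <- intersect(labels, epochs)
  ev_list <- list(); sum_list <- list(); sigma <- numeric(0)
  for (lb in labels) {
    seg <- trace_epoch(trace, lb)
    row <- ep[ep$label == lb, ]
    st <- schedule$stim_times
    st <- st[st >= row$start & st < row$end]
    det <- detect_trace(seg$F, seg$rate, params, time = seg$time,
                        stim_times = st, kinetics = kinetics)
    if (nrow(det$events)) det$events$epoch <- lb
    ev_list[[lb]] <- det$events
    sigma[lb] <- det$sigma
    smry <- summarize_synapse(det$events, st, (row$end - row$start) / 60)
    smry$epoch <- lb
    smry$duration_min <- (row$end - row$start) / 60
    smry$n_stim <- length(st)
    smry$noise_sd <- det$sigma
    smry$baseline_level <- baseline_level(det$detrended, seg$rate, seg$time,
                                          det$events, st, strict = FALSE)
    sum_list[[lb]] <- smry
  }
  ev <- do.call(rbind, ev_list[vapply(ev_list, nrow, 0L) > 0])
  if (is.null(ev)) ev <- cbind(ev_list[[1]][0, ], epoch = character(0))
  rownames(ev) <- NULL
  list(events = ev, sigma = sigma, summaries = do.call(rbind, sum_list))
}
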