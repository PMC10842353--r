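#' Baseline fluorescence level of a trace
#'
#' The baseline Ca level is the mean detrended fluorescence during times of
#' minimal to no transients: frames inside detected-event extents or within
#' 1 s after a stimulus are excluded.
#'
#' @param d Detrended fluorescence vector (slope removed, absolute level
#'   retained, see [subtract_background()]).
#' @param rate Sampling rate, frames/s.
#' @param time Frame start times, s.
#' @param events Detection table (may have zero rows).
#' @param stim_times Stimulus times, s.
#' @param post_stim Seconds excluded after each stimulus.
#' @param strict Error when fewer than 50 event-free frames remain (default);
#'   with `strict = FALSE` returns `NA` instead.
#' @return Mean baseline level (F units); attribute `n_frames` gives the
#'   number of frames used.
#' @export
baseline_level <- function(d, rate, time = NULL, events = NULL,
                           stim_times = numeric(0), post_stim = 1,
                           strict = TRUE) {
  n <- length(d)
  if (is.null(time)) time <- (seq_len(n) - 1) / rate
  mask <- exclusion_mask(n, time, events, stim_times, post_stim)
  k <- sum(!mask)
  if (k < 50) {
    if (strict) stop("fewer than 50 event-free frames for the baseline level")
    return(structure(NA_real_, n_frames = k))
  }
  structure(mean(d[!mask]), n_frames = k)
}

#' Pooled cohort metrics for one epoch pair
#'
#' Runs the detection pipeline on every ROI of a simulated (or recorded)
#' cohort and pools the six signal-class metrics over ROIs for the named
#' spontaneous and evoked epochs: evoked likelihood (pooled over all stimuli),
#' mean evoked amplitude (dF), spontaneous frequency (events/ROI/min, pooled),
#' mean spontaneous amplitude (dF), mean baseline level and mean noise SD
#' (both from the spontaneous epoch).
#'
#' @param cohort Result of [simulate_cohort()] (or a compatible list with
#'   `traces`).
#' @param schedule The session [stim_schedule()].
#' @param spont_epoch,evoked_epoch Epoch labels to analyze.
#' @param params [detection_params()].
#' @return One-row `data.frame` of pooled metrics plus bookkeeping counts.
#' @export
pooled_epoch_metrics <- function(cohort, schedule, spont_epoch, evoked_epoch,
                                 params = detection_params()) {
  n_hit <- 0L; n_stim <- 0L; n_spont <- 0L; min_spont <- 0
  amp_e <- numeric(0); amp_s <- numeric(0)
  base <- numeric(0); noise <- numeric(0)
  for (tr in cohort$traces) {
    det <- detect_session(tr, schedule, params,
                          epochs = c(spont_epoch, evoked_epoch))
    sm <- det$summaries
    sp <- sm[sm$epoch == spont_epoch, ]
    evk <- sm[sm$epoch == evoked_epoch, ]
    if (nrow(evk)) {
      n_hit <- n_hit + round(evk$evoked_likelihood * evk$n_stim)
      n_stim <- n_stim + evk$n_stim
      ev <- det$events
      amp_e <- c(amp_e, ev$amplitude_df[ev$class == "evoked" &
                                          ev$epoch == evoked_epoch])
    }
    if (nrow(sp)) {
      n_spont <- n_spont + sp$n_spont
      min_spont <- min_spont + sp$duration_min
      ev <- det$events
      amp_s <- c(amp_s, ev$amplitude_df[ev$class == "spontaneous" &
                                          ev$epoch == spont_epoch])
      base <- c(base, sp$baseline_level)
      noise <- c(noise, sp$noise_sd)
    }
  }
  mean_or_na <- function(x) if (length(x)) mean(x, na.rm = TRUE) else NA_real_
  data.frame(
    evoked_likelihood = if (n_stim) n_hit / n_stim else NA_real_,
    evoked_amplitude = mean_or_na(amp_e),
    spont_frequency = if (min_spont > 0) n_spont / min_spont else NA_real_,
    spont_amplitude = mean_or_na(amp_s),
    baseline_level = mean_or_na(base),
    noise_sd = mean_or_na(noise),
    n_roi = length(cohort$traces), n_stim = n_stim, n_spont = n_spont,
    roi_minutes = min_spont
  )
}

#' Before/after epoch comparison with the two normalization conventions
#'
#' `gcamp` mode divides each ROI's after-treatment value by the coverslip
#' average of the before values (spontaneous transients are too rare to
#' normalize synapse by synapse); `iglusnfr` mode normalizes synapse by
#' synapse, so every before value maps to 1. ROIs whose denominator is zero
#' (or missing) are flagged and excluded, and the count is reported.
#'
#' @param before,after `data.frame`s with matched ROI sets: column `roi`,
#'   optional `coverslip`, plus the metric columns named in `metrics`.
#' @param mode `"gcamp"` or `"iglusnfr"`.
#' @param metrics Character vector of metric column names to compare.
#' @return List: `per_roi` (ratios per ROI and metric), `coverslip`
#'   (per-coverslip mean ratios), `mean` (named overall mean ratios),
#'   `n_excluded` (named count of zero-denominator ROIs per metric).
#' @export
compare_epochs <- function(before, after, mode = c("gcamp", "iglusnfr"),
                           metrics = intersect(names(before),
                                               c("spont_frequency",
                                                 "evoked_likelihood",
                                                 "amp_evoked_df",
                                                 "amp_spont_df",
                                                 "baseline_level",
                                                 "noise_sd"))) {
  mode <- match.arg(mode)
  stopifnot("roi" %in% names(before), "roi" %in% names(after))
  if (!setequal(before$roi, after$roi)) stop("before/after ROI sets differ")
  after <- after[match(before$roi, after$roi), , drop = FALSE]
  if (!"coverslip" %in% names(before)) before$coverslip <- 1L
  cs <- before$coverslip

  per_roi <- data.frame(roi = before$roi, coverslip = cs)
  n_excluded <- stats::setNames(integer(length(metrics)), metrics)
  for (m in metrics) {
    denom <- if (mode == "gcamp") {
      stats::ave(before[[m]], cs, FUN = function(x) mean(x, na.rm = TRUE))
    } else {
      before[[m]]
    }
    bad <- !is.finite(denom) | denom == 0
    n_excluded[m] <- sum(bad)
    r <- after[[m]] / denom
    r[bad] <- NA_real_
    per_roi[[m]] <- r
  }
  coverslip <- stats::aggregate(per_roi[metrics],
                                by = list(coverslip = per_roi$coverslip),
                                FUN = function(x) mean(x, na.rm = TRUE))
  overall <- vapply(metrics, function(m) mean(per_roi[[m]], na.rm = TRUE),
                    numeric(1))
  list(per_roi = per_roi, coverslip = coverslip, mean = overall,
       n_excluded = n_excluded, mode = mode)
}

#' Photobleaching susceptibility matrix
#'
#' For each bleach protocol, compares the after/before ratio of every metric
#' with the matched no-bleach control's ratio; a metric is susceptible when
#' its ratio falls below the control ratio by more than `margin`. The three
#' class-level calls use the primary metric of each signal class (evoked:
#' likelihood; spontaneous: frequency; baseline: level).
#'
#' @param sessions Named list; each element (one per protocol, e.g. `rest`,
#'   `stim`, `highk`) is a list with one-row `before` and `after` metric
#'   tables from [pooled_epoch_metrics()].
#' @param control The matched no-bleach control, same structure.
#' @param margin Susceptibility margin on the ratio scale (default 0.10).
#' @return `data.frame` with one row per (metric, protocol): `ratio`,
#'   `control_ratio`, `diff`, `susceptible`, plus `class` and `primary`.
#' @export
bleach_susceptibility <- function(sessions, control, margin = 0.10) {
  if (is.null(control)) stop("a matched no-bleach control arm is required")
  metrics <- c("evoked_likelihood", "evoked_amplitude",
               "spont_frequency", "spont_amplitude",
               "baseline_level", "noise_sd")
  classes <- c("evoked", "evoked", "spontaneous", "spontaneous",
               "baseline", "baseline")
  primary <- metrics %in% c("evoked_likelihood", "spont_frequency",
                            "baseline_level")
  ratio_of <- function(arm, m) arm$after[[m]] / arm$before[[m]]
  out <- list()
  for (pn in names(sessions)) {
    r <- vapply(metrics, ratio_of, numeric(1), arm = sessions[[pn]])
    r0 <- vapply(metrics, ratio_of, numeric(1), arm = control)
    out[[pn]] <- data.frame(
      protocol = pn, metric = metrics, class = classes, primary = primary,
      ratio = r, control_ratio = r0, diff = r - r0,
      susceptible = (r - r0) < -margin
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fluorescence recovery after photobleaching
#'
#' Expresses each metric measured after a recovery period as a fraction of
#' its pre-bleach value, per recovery duration. Under the single-rate
#' exchange model the unbleached fraction follows
#' `u(t) = 1 - (1 - u0) * exp(-k_exchange * t)`.
#'
#' @param sessions List with one element per recovery duration, each a list
#'   with one-row `before` and `after` tables from [pooled_epoch_metrics()].
#' @param durations Recovery durations, minutes, same length as `sessions`;
#'   must be sorted increasing.
#' @param metrics Metric columns to report.
#' @return `data.frame`: `duration_min` plus one recovery-fraction column per
#'   metric.
#' @export
recovery_curve <- function(sessions, durations,
                           metrics = c("evoked_likelihood",
                                       "evoked_amplitude",
                                       "baseline_level")) {
  stopifnot(length(sessions) == length(durations))
  if (is.unsorted(durations, strictly = TRUE)) {
    stop("recovery durations must be strictly increasing")
  }
  rows <- lapply(seq_along(sessions), function(i) {
    fr <- vapply(metrics, function(m) {
      sessions[[i]]$after[[m]] / sessions[[i]]$before[[m]]
    }, numeric(1))
    cbind(data.frame(duration_min = durations[i]), as.data.frame(t(fr)))
  })
  do.call(rbind, rows)
}
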