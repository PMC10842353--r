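#' Stimulus and epoch schedule
#'
#' A schedule describes one imaging session: an ordered, non-overlapping set of
#' epochs covering `[0, duration]`, each with an illumination state
#' (`imaging`, `bleach`, or `dark`), a stimulation flag and a high-K+ flag,
#' plus the absolute stimulus times. Frames exist only for `imaging` epochs;
#' `bleach` and `dark` epochs advance the photobleaching/exchange state
#' without producing data.
#'
#' @param duration Total session length, s.
#' @param epochs `data.frame` with columns `label`, `start`, `end` (s),
#'   `illumination` (one of `"imaging"`, `"bleach"`, `"dark"`), `stimulated`
#'   (logical), `highk` (logical).
#' @param stim_times Numeric vector of stimulus times (s), strictly
#'   increasing. Defaults to regular trains in every stimulated epoch, see
#'   `stim_interval`.
#' @param stim_interval Inter-stimulus interval (s) used to fill stimulated
#'   epochs when `stim_times` is not given. Default 10 s.
#' @return An object of class `stim_schedule`.
#' @export
stim_schedule <- function(duration, epochs, stim_times = NULL,
                          stim_interval = 10) {
  stopifnot(is.data.frame(epochs))
  need <- c("label", "start", "end", "illumination", "stimulated", "highk")
  if (!all(need %in% names(epochs))) {
    stop("epochs must have columns ", paste(need, collapse = ", "))
  }
  epochs <- epochs[order(epochs$start), , drop = FALSE]
  rownames(epochs) <- NULL
  if (any(epochs$end <= epochs$start)) stop("epochs must have end > start")
  if (nrow(epochs) > 1 &&
      any(abs(epochs$start[-1] - epochs$end[-nrow(epochs)]) > 1e-9)) {
    stop("epochs must be contiguous and non-overlapping")
  }
  if (abs(epochs$start[1]) > 1e-9 ||
      abs(epochs$end[nrow(epochs)] - duration) > 1e-9) {
    stop("epochs must cover [0, duration]")
  }
  if (!all(epochs$illumination %in% c("imaging", "bleach", "dark"))) {
    stop("illumination must be imaging, bleach or dark")
  }
  if (is.null(stim_times)) {
    stim_times <- unlist(lapply(which(epochs$stimulated), function(i) {
      seq(epochs$start[i] + stim_interval / 2, epochs$end[i] - 1e-9,
          by = stim_interval)
    }))
    if (is.null(stim_times)) stim_times <- numeric(0)
  }
  stim_times <- as.numeric(stim_times)
  if (length(stim_times) > 1 && any(diff(stim_times) <= 0)) {
    stop("stim_times must be strictly increasing")
  }
  if (length(stim_times) && (min(stim_times) < 0 || max(stim_times) > duration)) {
    stop("stim_times must lie within [0, duration]")
  }
  structure(list(duration = duration, epochs = epochs,
                 stim_times = stim_times),
            class = "stim_schedule")
}

#' Single-epoch recording schedules
#'
#' `schedule_spont()` is one continuous imaging epoch without stimulation
#' (spontaneous recording); `schedule_evoked()` delivers `n_stim` stimuli at
#' `stim_interval` (default every 10 s).
#'
#' @param duration Recording length, s.
#' @param n_stim Number of stimuli.
#' @param stim_interval Inter-stimulus interval, s.
#' @param label Epoch label.
#' @export
schedule_spont <- function(duration, label = "spont") {
  stim_schedule(duration, data.frame(
    label = label, start = 0, end = duration,
    illumination = "imaging", stimulated = FALSE, highk = FALSE
  ))
}

#' @rdname schedule_spont
#' @export
schedule_evoked <- function(n_stim, stim_interval = 10, label = "evoked") {
  duration <- n_stim * stim_interval
  stim_schedule(duration, data.frame(
    label = label, start = 0, end = duration,
    illumination = "imaging", stimulated = TRUE, highk = FALSE
  ), stim_interval = stim_interval)
}

#' Photobleaching session schedule
#'
#' Builds the canonical bleach protocol: spontaneous and evoked baseline
#' recordings, a bleach (or control wait) period, an optional dark recovery
#' period, then matched post recordings. The bleach period is at rest
#' (`protocol = "rest"`), with stimulation (`"stim"`), with high-K+ perfusion
#' (`"highk"`), or replaced by a dark wait of identical length for the matched
#' no-bleach control (`"control"`).
#'
#' @param protocol One of `"control"`, `"rest"`, `"stim"`, `"highk"`.
#' @param t_spont,t_evoked Durations (s) of the spontaneous and evoked
#'   recording epochs (defaults 180 s and 120 s).
#' @param t_bleach Bleach/wait duration, s (default 1800 s = 30 min).
#' @param t_recovery Dark recovery duration after the bleach period, s.
#' @param stim_interval Inter-stimulus interval, s.
#' @return A [stim_schedule()].
#' @export
schedule_bleach_session <- function(protocol = c("control", "rest", "stim", "highk"),
                                    t_spont = 180, t_evoked = 120,
                                    t_bleach = 1800, t_recovery = 0,
                                    stim_interval = 10) {
  protocol <- match.arg(protocol)
  illum <- if (protocol == "control") "dark" else "bleach"
  stimmed <- protocol == "stim"
  highk <- protocol == "highk"
  rows <- list(
    c("before_spont", t_spont, "imaging", FALSE, FALSE),
    c("before_evoked", t_evoked, "imaging", TRUE, FALSE),
    c("bleach", t_bleach, illum, stimmed, highk)
  )
  if (t_recovery > 0) {
    rows <- c(rows, list(c("recovery", t_recovery, "dark", FALSE, FALSE)))
  }
  rows <- c(rows, list(
    c("after_spont", t_spont, "imaging", FALSE, FALSE),
    c("after_evoked", t_evoked, "imaging", TRUE, FALSE)
  ))
  dur <- cumsum(as.numeric(vapply(rows, `[[`, "", 2)))
  epochs <- data.frame(
    label = vapply(rows, `[[`, "", 1),
    start = c(0, dur[-length(dur)]),
    end = dur,
    illumination = vapply(rows, `[[`, "", 3),
    stimulated = as.logical(vapply(rows, `[[`, "", 4)),
    highk = as.logical(vapply(rows, `[[`, "", 5))
  )
  stim_schedule(dur[length(dur)], epochs, stim_interval = stim_interval)
}

#' Frame times of the imaging epochs
#'
#' Frame `i` of an epoch covers `[start + (i-1)/rate, start + i/rate)`; its
#' timestamp is the frame start time.
#' @noRd
frame_table <- function(schedule, rate) {
  ep <- schedule$epochs
  img <- which(ep$illumination == "imaging")
  if (!length(img)) stop("schedule has no imaging epochs")
  out <- lapply(img, function(i) {
    n <- round((ep$end[i] - ep$start[i]) * rate)
    data.frame(
      time = ep$start[i] + (seq_len(n) - 1) / rate,
      epoch = ep$label[i],
      highk = ep$highk[i]
    )
  })
  do.call(rbind, out)
}

#' Read / write a schedule as JSON
#' @param schedule A [stim_schedule()].
#' @param path File path.
#' @export
write_schedule <- function(schedule, path) {
  jsonlite::write_json(unclass(schedule), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  stim_schedule(raw$duration, as.data.frame(raw$epochs),
                stim_times = raw$stim_times)
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("<stim_schedule> %.0f s, %d epochs, %d stimuli\n",
              x$duration, nrow(x$epochs), length(x$stim_times)))
  print(x$epochs)
  invisible(x)
}
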