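#' Coverslip-level aggregation of synapse metrics
#'
#' Statistics are computed on coverslip averages rather than pooled synapses.
#' Spontaneous frequency is averaged two ways, mirroring the all-synapses
#' versus active-synapses distinction: `spont_frequency_all` includes silent
#' ROIs at frequency 0, `spont_frequency_active` averages active ROIs only.
#'
#' @param synapses `data.frame` with one row per ROI: `coverslip`, `roi`,
#'   `spont_frequency`, `active`, plus any further numeric metric columns,
#'   which are averaged per coverslip (`NA`s dropped).
#' @return `data.frame`, one row per coverslip: `n_roi`, `n_active`,
#'   `silent_fraction`, both frequency means, and the mean of every other
#'   numeric metric.
#' @export
aggregate_coverslips <- function(synapses) {
  stopifnot(all(c("coverslip", "spont_frequency", "active") %in%
                  names(synapses)))
  split_cs <- split(synapses, synapses$coverslip)
  if (any(vapply(split_cs, nrow, 0L) == 0)) stop("empty coverslip")
  other <- setdiff(names(synapses)[vapply(synapses, is.numeric, TRUE)],
                   c("coverslip", "roi", "spont_frequency"))
  rows <- lapply(split_cs, function(df) {
    act <- df$spont_frequency[df$active]
    base <- data.frame(
      coverslip = df$coverslip[1],
      n_roi = nrow(df),
      n_active = sum(df$active),
      silent_fraction = mean(!df$active),
      spont_frequency_all = mean(df$spont_frequency),
      spont_frequency_active = if (length(act)) mean(act) else NA_real_
    )
    for (m in other) base[[m]] <- mean(df[[m]], na.rm = TRUE)
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate-detect-aggregate pipeline
#'
#' End-to-end driver: simulates a cohort under one schedule, runs the
#' detection pipeline on every ROI and imaging epoch, builds the per-synapse
#' and per-coverslip tables, and (optionally) writes everything plus a
#' manifest with the seed and config hash to `out_dir`.
#'
#' @param config A [bouton_config()].
#' @param schedule A [stim_schedule()].
#' @param n_roi,silent_fraction,n_coverslip Cohort structure, see
#'   [simulate_cohort()].
#' @param params [detection_params()].
#' @param seed Master seed.
#' @param out_dir Output directory (`NULL` = don't write).
#' @return List: `cohort`, `events` (all ROIs), `synapses` (per ROI x epoch),
#'   `coverslips` (per coverslip x epoch), `manifest`.
#' @export
run_pipeline <- function(config, schedule, n_roi = 10, silent_fraction = 0,
                         n_coverslip = 1, params = detection_params(),
                         seed = config$seed, out_dir = NULL) {
  cohort <- simulate_cohort(config, schedule, n_roi, silent_fraction,
                            n_coverslip, seed = seed)
  ev_list <- list(); syn_list <- list()
  for (i in seq_len(n_roi)) {
    det <- detect_session(cohort$traces[[i]], schedule, params)
    if (nrow(det$events)) {
      det$events$roi <- i
      ev_list[[length(ev_list) + 1L]] <- det$events
    }
    sm <- det$summaries
    sm$roi <- i
    sm$coverslip <- cohort$rois$coverslip[i]
    syn_list[[i]] <- sm
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else NULL
  synapses <- do.call(rbind, syn_list)
  rownames(synapses) <- NULL
  coverslips <- do.call(rbind, lapply(split(synapses, synapses$epoch),
    function(df) {
      agg <- aggregate_coverslips(df)
      agg$epoch <- df$epoch[1]
      agg
    }))
  rownames(coverslips) <- NULL
  manifest <- list(
    package = "boutonca",
    version = as.character(utils::packageVersion("boutonca")),
    seed = seed, n_roi = n_roi, silent_fraction = silent_fraction,
    n_coverslip = n_coverslip,
    n_events = if (is.null(events)) 0L else nrow(events)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.json"))
    manifest$config_md5 <-
      unname(tools::md5sum(file.path(out_dir, "config.json")))
    write_schedule(schedule, file.path(out_dir, "schedule.json"))
    write_traces_csv(cohort$traces, file.path(out_dir, "traces.csv"))
    if (!is.null(events)) {
      utils::write.csv(events, file.path(out_dir, "events.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(synapses, file.path(out_dir, "synapses.csv"),
                     row.names = FALSE)
    utils::write.csv(coverslips, file.path(out_dir, "coverslips.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(cohort = cohort, events = events, synapses = synapses,
       coverslips = coverslips, manifest = manifest)
}

#' Write / read a cohort's traces as CSV
#'
#' One `time` column (s) plus one column per ROI, as exported by the imaging
#' pipeline.
#'
#' @param traces List of `fluor_trace` sharing one frame grid.
#' @param path File path.
#' @export
write_traces_csv <- function(traces, path) {
  df <- data.frame(time = traces[[1]]$time)
  for (i in seq_along(traces)) df[[paste0("roi_", i)]] <- traces[[i]]$F
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param rate Sampling rate of the stored traces, frames/s.
#' @export
read_traces_csv <- function(path, rate = 10) {
  df <- utils::read.csv(path)
  stopifnot(names(df)[1] == "time")
  lapply(seq_len(ncol(df) - 1), function(i) {
    structure(list(F = df[[i + 1]], time = df$time,
                   epoch = rep("recording", nrow(df)), rate = rate),
              class = "fluor_trace")
  })
}
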