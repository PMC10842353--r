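#!/usr/bin/env Rscript
# Cohort survey of detected presynaptic Ca transients: spontaneous
# frequencies (all vs active synapses), silent fraction, evoked likelihood,
# and class kinetics measured on event-triggered averages.
# Writes: results/cohort_summary.csv, results/class_kinetics.csv

suppressMessages(library(boutonca))
dir.create("results", showWarnings = FALSE)
seed <- 20230901

# --- spontaneous recordings: 200 ROIs, 10 min, 90% silent --------------------
cfg <- bouton_config(seed = seed)
sch_sp <- schedule_spont(600)
co <- simulate_cohort(cfg, sch_sp, n_roi = 200, silent_fraction = 0.9,
                      n_coverslip = 8, seed = seed)
syn <- do.call(rbind, lapply(seq_along(co$traces), function(i) {
  det <- detect_trace(co$traces[[i]]$F, cfg$sampling_rate, kinetics = FALSE)
  s <- summarize_synapse(det$events, numeric(0), 10)
  s$roi <- i; s$coverslip <- co$rois$coverslip[i]
  s
}))
agg <- aggregate_coverslips(syn)
message(sprintf(
  "Spontaneous: %.3f events/ROI/min over all synapses (active only: %.2f); %.0f%% of synapses silent",
  mean(agg$spont_frequency_all), mean(agg$spont_frequency_active, na.rm = TRUE),
  100 * mean(agg$silent_fraction)))

# --- evoked recordings: 50 ROIs, 60 stimuli at 10-s intervals ----------------
sch_ev <- schedule_evoked(60)
co_ev <- simulate_cohort(cfg, sch_ev, n_roi = 50, n_coverslip = 5,
                         seed = seed + 1)
lik <- vapply(co_ev$traces, function(tr) {
  det <- detect_trace(tr$F, cfg$sampling_rate, time = tr$time,
                      stim_times = sch_ev$stim_times, kinetics = FALSE)
  summarize_synapse(det$events, sch_ev$stim_times, 10)$evoked_likelihood
}, numeric(1))
message(sprintf(
  "Evoked: mean likelihood to stimulation %.2f; %.0f%% of synapses respond to >=90%% of stimuli",
  mean(lik), 100 * mean(lik >= 0.9)))

write.csv(cbind(epoch = "survey", agg,
                evoked_likelihood = mean(lik),
                frac_high_fidelity = mean(lik >= 0.9)),
          "results/cohort_summary.csv", row.names = FALSE)

# --- class kinetics on event-triggered averages ------------------------------
# active boutons at an elevated spontaneous rate so both classes contribute
# enough isolated events to average
cfg_k <- bouton_config(lambda_spont = 2, seed = seed + 2)
sch_k <- schedule_bleach_session("control", t_spont = 300, t_evoked = 200,
                                 t_bleach = 1)
co_k <- simulate_cohort(cfg_k, sch_k, n_roi = 25, seed = seed + 2)
traces <- list(); evs <- list()
for (tr in co_k$traces) {
  for (lb in c("before_spont", "before_evoked")) {
    seg <- trace_epoch(tr, lb)
    row <- sch_k$epochs[sch_k$epochs$label == lb, ]
    st <- sch_k$stim_times[sch_k$stim_times >= row$start &
                             sch_k$stim_times < row$end]
    det <- detect_trace(seg$F, seg$rate, time = seg$time, stim_times = st)
    traces[[length(traces) + 1L]] <- det$smoothed
    if (nrow(det$events)) {
      det$events$trace <- length(traces)
      evs[[length(evs) + 1L]] <- det$events
    }
  }
}
ev <- do.call(rbind, evs)
kin <- do.call(rbind, lapply(c("evoked", "spontaneous"), function(cl) {
  eta <- event_triggered_average(traces, ev, cfg$sampling_rate,
                                 pre = 0.3, post = 2.5, class = cl)
  cbind(class = cl, waveform_kinetics(eta, cfg$sampling_rate))
}))
kin$amplitude_dff <- vapply(kin$class, function(cl) {
  mean(ev$amplitude_dff[ev$class == cl]) }, numeric(1))
message(sprintf(
  "Kinetics (averaged events): rise %.2f s (spont) vs %.2f s (evoked); decay %.2f vs %.2f s; amplitude %.2f vs %.2f dF/F",
  kin$rise_s[2], kin$rise_s[1], kin$decay_s[2], kin$decay_s[1],
  kin$amplitude_dff[2], kin$amplitude_dff[1]))
write.csv(kin, "results/class_kinetics.csv", row.names = FALSE)
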