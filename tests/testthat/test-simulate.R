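test_that("noise-free trace is exactly F0 between transients", {
  cfg <- bouton_config(p_evoked = 1, lambda_spont = 0, shot_rate = 0,
                       sigma_noise = 0, cv_evoked = 0)
  sch <- schedule_evoked(3)
  sim <- simulate_trace(cfg, sch)
  ev <- sim$truth$events
  expect_equal(nrow(ev), 3)
  expect_true(all(ev$class == "evoked"))
  expect_equal(ev$time, sch$stim_times)
  expect_equal(length(sim$trace$F), 30 * 10)
  pre <- sim$trace$time < sch$stim_times[1]
  expect_equal(sim$trace$F[pre], rep(cfg$F0, sum(pre)))
  # every ground-truth event corresponds to an additive kernel in the trace
  i1 <- which(sim$trace$time >= ev$time[1])[1:8]
  expect_equal(sim$trace$F[i1],
               cfg$F0 * (1 + cfg$A_evoked *
                 transient_kernel(sim$trace$time[i1] - ev$time[1],
                                  cfg$tau_rise_evoked, cfg$tau_decay)),
               tolerance = 1e-12)
})

test_that("spontaneous counts follow the Poisson closed form and scale linearly", {
  sch <- schedule_spont(600)
  counts <- function(lambda, seeds) {
    vapply(seeds, function(s) {
      cfg <- bouton_config(lambda_spont = lambda, shot_rate = 0,
                           sigma_noise = 0, seed = s)
      nrow(simulate_trace(cfg, sch)$truth$events)
    }, numeric(1))
  }
  n1 <- counts(0.04, 1:500)
  mu <- 0.04 * 10 # 10-min trace
  se <- sqrt(mu / 500)
  expect_lt(abs(mean(n1) - mu), 3 * se)
  n2 <- counts(0.08, 501:1000)
  expect_lt(abs(mean(n2) - 2 * mu), 3 * sqrt(2 * mu / 500))
})

test_that("identical config and seed give bit-identical output", {
  cfg <- bouton_config(seed = 123)
  sch <- schedule_bleach_session("stim")
  a <- simulate_trace(cfg, sch)
  b <- simulate_trace(cfg, sch)
  expect_identical(a$trace$F, b$trace$F)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("shot-noise baseline has the Campbell mean", {
  cfg <- bouton_config(lambda_spont = 0, sigma_noise = 0, seed = 5)
  sim <- simulate_trace(cfg, schedule_spont(600))
  expected <- cfg$F0 * (1 + baseline_occupancy(cfg))
  expect_lt(abs(mean(sim$trace$F) - expected) / expected, 0.02)
})

test_that("bleached pools scale the fluorescent amplitude of events", {
  cfg <- bouton_config(seed = 9, lambda_spont = 0.5)
  sch <- schedule_bleach_session("highk")
  sim <- simulate_trace(cfg, sch)
  uu <- sim$truth$u
  ev <- sim$truth$events
  after <- ev[ev$time > uu$start[uu$label == "after_spont"], ]
  if (nrow(after)) {
    epo <- findInterval(after$time, uu$start) # epoch containing each event
    u_exp <- ifelse(after$class == "evoked", uu$uE[epo], uu$uS[epo])
    expect_equal(after$amplitude_fluor, after$amplitude * u_exp,
                 tolerance = 1e-9)
  }
  # unbleached fractions always within [0,1]
  expect_true(all(uu[, c("uE", "uS", "uB")] >= 0 &
                    uu[, c("uE", "uS", "uB")] <= 1))
})

test_that("matched schedules draw identical events in shared epochs", {
  cfg <- bouton_config(seed = 321, lambda_spont = 1)
  a <- simulate_trace(cfg, schedule_bleach_session("rest"))
  b <- simulate_trace(cfg, schedule_bleach_session("control"))
  ea <- a$truth$events; eb <- b$truth$events
  expect_equal(ea$time, eb$time)
  expect_equal(ea$amplitude, eb$amplitude)
})

test_that("cohorts assign silent boutons and coverslips deterministically", {
  cfg <- bouton_config()
  co <- simulate_cohort(cfg, schedule_spont(120), n_roi = 20,
                        silent_fraction = 0.5, n_coverslip = 4, seed = 7)
  expect_equal(sum(co$rois$silent), 10)
  expect_equal(sort(unique(co$rois$coverslip)), 1:4)
  for (i in which(co$rois$silent)) {
    expect_equal(nrow(co$truths[[i]]$events), 0)
  }
  co2 <- simulate_cohort(cfg, schedule_spont(120), n_roi = 20,
                         silent_fraction = 0.5, n_coverslip = 4, seed = 7)
  expect_identical(co$traces[[3]]$F, co2$traces[[3]]$F)
})

test_that("detected spontaneous frequency recovers rates in the reported band", {
  # configs with rates inside 0.01-0.05 events/ROI/min yield detected cohort
  # frequencies in the same band
  lam <- 0.03
  n_roi <- 60
  sch <- schedule_spont(600)
  co <- simulate_cohort(bouton_config(lambda_spont = lam), sch, n_roi,
                        seed = 77)
  n_ev <- sum(vapply(co$traces, function(tr) {
    nrow(detect_trace(tr$F, tr$rate, kinetics = FALSE)$events)
  }, numeric(1)))
  freq <- n_ev / (n_roi * 10)
  expect_gte(freq, 0.01)
  expect_lte(freq, 0.05)
})
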