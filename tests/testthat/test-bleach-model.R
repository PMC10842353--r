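test_that("bleach update obeys its closed forms", {
  cfg <- bouton_config(k_bleach = 0.05, k_exchange = 0)
  u <- c(0.8, 0.5, 1)
  # no fluorescence, no exchange: nothing changes
  expect_equal(apply_bleach_step(u, c(0, 0, 0), 1000, cfg), u)
  # half-life of a fully fluorescent pool
  u2 <- apply_bleach_step(1, 1, log(2) / 0.05, cfg)
  expect_equal(u2, 0.5, tolerance = 1e-12)
  # asymptote with exchange: kx / (kx + kb * duty)
  cfg2 <- bouton_config(k_bleach = 0.05, k_exchange = 0.6) # 0.01/s
  u3 <- apply_bleach_step(1, 0.5, 1e6, cfg2)
  expect_equal(u3, 0.01 / (0.01 + 0.025), tolerance = 1e-9)
  expect_error(apply_bleach_step(1.2, 1, 1, cfg), "\\[0,1\\]")
  expect_error(apply_bleach_step(0.5, 1, -1, cfg), "dt")
})

test_that("fluorophore mass is conserved and fractions stay in [0,1]", {
  cfg <- bouton_config(k_exchange = 0)
  set.seed(4)
  u <- runif(3)
  for (i in 1:50) {
    dt <- runif(1, 0.1, 5000) # any step size: exact update, no Euler drift
    u_new <- apply_bleach_step(u, runif(3), dt, cfg)
    expect_true(all(u_new >= 0 & u_new <= 1))
    expect_true(all(u_new <= u + 1e-12)) # without exchange, never increases
    u <- u_new
  }
})

test_that("duty cycles map epoch conditions to pool fluorescence", {
  cfg <- bouton_config()
  rest <- duty_cycles(list(stimulated = FALSE, highk = FALSE), cfg)
  expect_equal(unname(rest["E"]), 0)
  expect_equal(duty_cycles(list(stimulated = TRUE, highk = TRUE), cfg),
               c(E = 1, S = 1, B = 1))
  # stimulated duty: numerically integrated kernel area over the
  # inter-stimulus interval, scaled by response probability
  stim <- duty_cycles(list(stimulated = TRUE, highk = FALSE), cfg,
                      stim_interval = 10)
  tt <- seq(0, 10, by = 1e-4)
  occ <- sum(transient_kernel(tt, cfg$tau_rise_evoked, cfg$tau_decay)) * 1e-4
  expect_equal(unname(stim["E"]), cfg$p_evoked * occ / 10, tolerance = 1e-3)
  expect_lt(stim["S"], 0.01) # the basis of sPreCT bleach resistance
})

test_that("bleaching at rest spares the evoked pool but not the baseline pool", {
  cfg <- bouton_config()
  uu <- unbleached_timecourse(schedule_bleach_session("rest", t_bleach = 1800),
                              cfg)
  after <- uu[uu$label == "after_spont", ]
  expect_gt(after$uE, 0.95)
  expect_gt(after$uS, 0.9)
  expect_lt(after$uB, 0.1)
  # monotone: non-increasing during bleach, non-decreasing during dark
  expect_lte(uu$uB_end[3], uu$uB[3])
  uu2 <- unbleached_timecourse(
    schedule_bleach_session("stim", t_bleach = 1800, t_recovery = 7200), cfg)
  rec <- uu2[uu2$label == "recovery", ]
  expect_gte(rec$uE_end, rec$uE) # non-decreasing during dark recovery
  uu3 <- unbleached_timecourse(schedule_bleach_session("stim"), cfg)
  expect_lt(uu3$uE[uu3$label == "after_spont"], 0.25)
  expect_gt(uu2$uE[uu2$label == "after_spont"],
            uu3$uE[uu3$label == "after_spont"])
})
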