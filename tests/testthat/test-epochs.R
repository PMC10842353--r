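test_that("synapse summaries follow their defining arithmetic", {
  ev <- data.frame(class = rep("evoked", 20), stim_index = 1:20,
                   amplitude_df = 50, amplitude_dff = 0.5)
  s <- summarize_synapse(ev, stim_times = seq(5, 195, by = 10),
                         duration_min = 200 / 60)
  expect_equal(s$evoked_likelihood, 1)
  sp <- data.frame(class = rep("spontaneous", 3), stim_index = NA_integer_,
                   amplitude_df = 40, amplitude_dff = 0.4)
  s2 <- summarize_synapse(sp, stim_times = numeric(0), duration_min = 10)
  expect_equal(s2$spont_frequency, 0.3)
  expect_true(is.na(s2$evoked_likelihood)) # undefined, not zero
  expect_true(s2$active)
})

test_that("baseline level averages event-free, stimulus-free frames", {
  expect_equal(as.numeric(baseline_level(rep(5, 600), 10)), 5)
  # shot-noise level recovered within 2% of the Campbell mean (noise-free)
  cfg <- bouton_config(lambda_spont = 0, sigma_noise = 0, seed = 14)
  sim <- simulate_trace(cfg, schedule_spont(600))
  lvl <- baseline_level(sim$trace$F, 10)
  expect_lt(abs(lvl - cfg$F0 * (1 + baseline_occupancy(cfg))) /
              (cfg$F0 * (1 + baseline_occupancy(cfg))), 0.02)
  expect_error(baseline_level(rep(1, 40), 10), "50")
})

test_that("shot-rate block lowers baseline level and noise SD together", {
  run <- function(block) {
    cfg <- apply_treatment(bouton_config(lambda_spont = 0, seed = 15),
                           "vgcc", block)
    sim <- simulate_trace(cfg, schedule_spont(600))
    d <- subtract_background(sim$trace$F, 10)
    c(level = as.numeric(baseline_level(d, 10)),
      noise = estimate_noise_sd(d, 10))
  }
  m <- sapply(c(0, 0.5, 0.9), run)
  expect_true(all(diff(m["level", ]) < 0))
  expect_true(all(diff(m["noise", ]) < 0))
})

test_that("epoch comparison implements both normalization conventions", {
  b <- data.frame(roi = 1:6, coverslip = rep(1:2, each = 3),
                  baseline_level = c(10, 20, 30, 40, 50, 60))
  a <- b
  ident <- compare_epochs(b, a, "gcamp", "baseline_level")
  expect_true(all(abs(ident$coverslip$baseline_level - 1) < 1e-12))
  ident2 <- compare_epochs(b, a, "iglusnfr", "baseline_level")
  expect_equal(unname(ident2$mean["baseline_level"]), 1)
  # iglusnfr: rescaling all before values leaves ratios unchanged
  b2 <- b; b2$baseline_level <- b$baseline_level * 17
  a2 <- a; a2$baseline_level <- a$baseline_level * 17
  sc <- compare_epochs(b2, a2, "iglusnfr", "baseline_level")
  expect_equal(sc$per_roi$baseline_level, ident2$per_roi$baseline_level)
  # gcamp: coverslip-mean ratio equals the ratio of means
  a3 <- b; a3$baseline_level <- c(5, 30, 25, 80, 25, 60)
  g <- compare_epochs(b, a3, "gcamp", "baseline_level")
  expect_equal(g$coverslip$baseline_level[1],
               mean(a3$baseline_level[1:3]) / mean(b$baseline_level[1:3]))
  # zero denominators are excluded and counted
  b4 <- data.frame(roi = 1:3, spont_frequency = c(0, 0.2, 0.4))
  a4 <- data.frame(roi = 1:3, spont_frequency = c(0.1, 0.1, 0.2))
  z <- compare_epochs(b4, a4, "iglusnfr", "spont_frequency")
  expect_equal(unname(z$n_excluded["spont_frequency"]), 1L)
  expect_equal(unname(z$mean["spont_frequency"]), 0.5)
})

test_that("susceptibility requires a margin below the matched control", {
  mk <- function(...) as.data.frame(list(...))
  base <- mk(evoked_likelihood = 0.9, evoked_amplitude = 100,
             spont_frequency = 0.1, spont_amplitude = 50,
             baseline_level = 130, noise_sd = 3.3)
  ctl <- list(before = base, after = base)
  eq <- bleach_susceptibility(list(rest = ctl), ctl)
  expect_false(any(eq$susceptible)) # zero bleach: nothing susceptible
  dim_base <- base; dim_base$baseline_level <- base$baseline_level * 0.7
  arm <- list(before = base, after = dim_base)
  m <- bleach_susceptibility(list(rest = arm), ctl)
  expect_true(m$susceptible[m$metric == "baseline_level"])
  expect_false(any(m$susceptible[m$metric != "baseline_level"]))
  # invariant to a global intensity rescaling of all traces
  sc <- function(x, f) { x$evoked_amplitude <- x$evoked_amplitude * f
    x$spont_amplitude <- x$spont_amplitude * f
    x$baseline_level <- x$baseline_level * f
    x$noise_sd <- x$noise_sd * f; x }
  arm2 <- list(before = sc(base, 3), after = sc(dim_base, 3))
  ctl2 <- list(before = sc(base, 3), after = sc(base, 3))
  m2 <- bleach_susceptibility(list(rest = arm2), ctl2)
  expect_equal(m$susceptible, m2$susceptible)
  expect_error(bleach_susceptibility(list(rest = arm), NULL), "control")
})

test_that("recovery fractions are ratios to the pre-bleach metric", {
  mk <- function(l) list(
    before = data.frame(evoked_likelihood = 0.9, evoked_amplitude = 100,
                        baseline_level = 130),
    after = data.frame(evoked_likelihood = 0.9 * l, evoked_amplitude = 100 * l,
                       baseline_level = 130 * l))
  cur <- recovery_curve(list(mk(0.1), mk(0.5), mk(0.95)), c(0, 60, 300))
  expect_equal(cur$evoked_amplitude, c(0.1, 0.5, 0.95))
  expect_error(recovery_curve(list(mk(1), mk(1)), c(60, 0)), "increasing")
})

test_that("coverslip aggregation mirrors the all-vs-active distinction", {
  syn <- data.frame(coverslip = 1, roi = 1:3,
                    spont_frequency = c(0, 0, 0.3),
                    active = c(FALSE, FALSE, TRUE))
  agg <- aggregate_coverslips(syn)
  expect_equal(agg$spont_frequency_all, 0.1)
  expect_equal(agg$spont_frequency_active, 0.3)
  expect_equal(agg$silent_fraction, 2 / 3)
  one <- aggregate_coverslips(data.frame(coverslip = 2, roi = 1,
                                         spont_frequency = 0.2, active = TRUE,
                                         baseline_level = 99))
  expect_equal(one$baseline_level, 99)
  # between-coverslip SD of the mean shrinks as 1/sqrt(ROIs per coverslip)
  set.seed(50)
  mk_tab <- function(m) data.frame(
    coverslip = rep(1:40, each = m), roi = 1,
    spont_frequency = rnorm(40 * m, 1, 0.3), active = TRUE)
  sd4 <- sd(aggregate_coverslips(mk_tab(4))$spont_frequency_all)
  sd16 <- sd(aggregate_coverslips(mk_tab(16))$spont_frequency_all)
  expect_lt(abs(sd4 / sd16 - 2), 0.6)
  # aggregation commutes with affine rescaling of level metrics
  syn2 <- data.frame(coverslip = rep(1:2, each = 3), roi = 1:6,
                     spont_frequency = runif(6), active = TRUE,
                     baseline_level = runif(6, 90, 110))
  agg_a <- aggregate_coverslips(syn2)
  syn2$baseline_level <- 2 * syn2$baseline_level + 5
  agg_b <- aggregate_coverslips(syn2)
  expect_equal(agg_b$baseline_level, 2 * agg_a$baseline_level + 5)
})

test_that("the pipeline is reproducible end to end", {
  cfg <- bouton_config(seed = 60)
  sch <- schedule_evoked(12)
  out1 <- run_pipeline(cfg, sch, n_roi = 3, out_dir = NULL)
  out2 <- run_pipeline(cfg, sch, n_roi = 3, out_dir = NULL)
  expect_identical(out1$events, out2$events)
  expect_identical(out1$coverslips, out2$coverslips)
  d <- tempfile()
  out3 <- run_pipeline(cfg, sch, n_roi = 3, out_dir = d)
  expect_true(all(file.exists(file.path(d, c("traces.csv", "events.csv",
                                             "synapses.csv", "coverslips.csv",
                                             "config.json", "manifest.json")))))
  back <- read_traces_csv(file.path(d, "traces.csv"))
  expect_equal(back[[2]]$F, out3$cohort$traces[[2]]$F, tolerance = 1e-9)
})
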