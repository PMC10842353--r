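test_that("smoothing is a centered moving average with shrunken edges", {
  expect_identical(smooth_trace(c(5, 1, 4), 1), c(5, 1, 4))
  expect_equal(smooth_trace(c(0, 0, 3, 0, 0), 3), c(0, 1, 1, 1, 0))
  expect_error(smooth_trace(1:10, 2), "odd")
  # interior variance reduction of white noise: sd / sqrt(3)
  set.seed(2)
  x <- rnorm(2e4)
  sm <- smooth_trace(x, 3)
  expect_lt(abs(sd(sm[2:(length(sm) - 1)]) - 1 / sqrt(3)), 0.02)
})

test_that("trailing baseline lags as the closed forms dictate", {
  expect_equal(moving_baseline(rep(3, 100), 10, 4), rep(3, 100))
  # step 0 -> 1 at frame k: baseline reaches 1 exactly 40 frames later (10 Hz)
  k <- 60
  x <- c(rep(0, k - 1), rep(1, 200 - k + 1))
  b <- moving_baseline(x, 10, 4)
  expect_lt(b[k + 39], 1)
  expect_equal(b[k + 40], 1)
  # unit ramp: trailing mean lags by (w + 1) / 2 frames
  r <- seq_len(300)
  br <- moving_baseline(r, 10, 4)
  expect_equal(r[100] - br[100], (40 + 1) / 2)
})

test_that("background subtraction removes slope but keeps the level", {
  set.seed(3)
  flat <- 100 + rnorm(1200)
  expect_lt(max(abs(subtract_background(flat, 10) - flat)), 1e-9 + 0.5)
  expect_identical(subtract_background(rep(7, 600), 10), rep(7, 600))
  # known drift slope recovered within 5% on an event-free trace
  m <- 0.01 # F units per frame
  drift <- 100 + m * (0:5999) + rnorm(6000)
  d <- subtract_background(drift, 10)
  fit <- coef(lm(d ~ seq_along(d)))[2]
  expect_lt(abs(fit) / m, 0.05)
  expect_lt(abs(mean(d[1:300]) - 100), 1)
  expect_error(subtract_background(rnorm(50), 10), "100 frames")
  expect_error(subtract_background(rnorm(200), 10), "percentile")
})

test_that("drift does not distort planted event amplitudes", {
  times <- c(30, 120, 250, 400, 510)
  base <- plant_events(6000, 10, times, amp = 30, noise_sd = 1, level = 100,
                       seed = 11)
  drifted <- base$s + 0.01 * (0:5999)
  amp_of <- function(f) {
    det <- detect_trace(f, 10)
    mean(det$events$amplitude_df)
  }
  a0 <- amp_of(base$s)
  a1 <- amp_of(drifted)
  expect_lt(abs(a1 - a0) / a0, 0.05)
})

test_that("robust noise SD resists planted events when masked", {
  set.seed(8)
  x <- rnorm(6000)
  est <- estimate_noise_sd(x, 10)
  expect_gt(est, 0.94); expect_lt(est, 1.06)
  expect_equal(estimate_noise_sd(rep(2, 600), 10), 0)
  pl <- plant_events(6000, 10, c(100, 300, 480), amp = 20, noise_sd = 1,
                     seed = 12)
  det <- detect_events(smooth_trace(pl$s, 3), 10, sigma = 1)
  mask <- exclusion_mask(6000, pl$time, det)
  masked <- estimate_noise_sd(pl$s, 10, mask)
  clean <- estimate_noise_sd(plant_events(6000, 10, numeric(0), 0,
                                          noise_sd = 1, seed = 12)$s, 10)
  expect_lt(abs(masked - clean) / clean, 0.05)
  expect_error(estimate_noise_sd(rnorm(60), 10, mask = rep(TRUE, 60)),
               "unmasked")
})

test_that("planted transients are detected and classified by time-locking", {
  expect_equal(nrow(detect_events(rep(0, 600), 10, sigma = 1)), 0)
  expect_error(detect_events(rep(0, 600), 10, sigma = 0), "degenerate")
  pl <- plant_events(600, 10, 20, amp = 10, noise_sd = 1, seed = 21)
  ev <- detect_events(smooth_trace(pl$s, 3), 10, sigma = 1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$class, "spontaneous")
  expect_lt(abs(ev$onset_s - 20), 0.2)
  # identical transient inside / outside the 0.3-s window after a stimulus
  pl2 <- plant_events(600, 10, c(10.1, 30.5), amp = 10, noise_sd = 0.5,
                      seed = 22)
  ev2 <- detect_events(smooth_trace(pl2$s, 3), 10, sigma = 0.5,
                       stim_times = c(10, 30))
  expect_equal(ev2$class, c("evoked", "spontaneous"))
  expect_equal(ev2$stim_index, c(1L, NA_integer_))
})

test_that("nearby onsets merge into a single event", {
  pl <- plant_events(600, 10, c(20, 20.4), amp = c(10, 14), noise_sd = 0.2,
                     seed = 23)
  ev <- detect_events(smooth_trace(pl$s, 3), 10, sigma = 0.2)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset_s - 20), 0.2)
  expect_gt(ev$peak_s, 20.3) # the larger, later peak wins
  # well-separated copies stay distinct
  pl2 <- plant_events(600, 10, c(20, 25), amp = 10, noise_sd = 0.2, seed = 24)
  expect_equal(nrow(detect_events(smooth_trace(pl2$s, 3), 10, sigma = 0.2)), 2)
})

test_that("detection has no history dependence beyond the merge gap", {
  # the same three events, permuted in time, yield the same matched set
  set.seed(31)
  times_a <- c(50, 200, 400)
  amps <- c(8, 12, 20)
  perm <- c(3, 1, 2)
  pl_a <- plant_events(6000, 10, times_a, amps, noise_sd = 1, seed = 32)
  pl_b <- plant_events(6000, 10, times_a, amps[perm], noise_sd = 1, seed = 32)
  ev_a <- detect_events(smooth_trace(pl_a$s, 3), 10, sigma = 1)
  ev_b <- detect_events(smooth_trace(pl_b$s, 3), 10, sigma = 1)
  expect_equal(nrow(ev_a), 3)
  expect_equal(nrow(ev_b), 3)
  expect_equal(ev_a$onset_idx, ev_b$onset_idx, tolerance = 1)
})

test_that("scanner agrees exactly with the naive reference on random traces", {
  set.seed(41)
  params <- detection_params()
  for (i in 1:60) {
    n <- 600
    n_ev <- rpois(1, 2)
    pl <- plant_events(n, 10, runif(n_ev, 2, 55), amp = runif(n_ev, 4, 15),
                       noise_sd = 1)
    s <- smooth_trace(pl$s, 3)
    st <- if (i %% 2) seq(5, 55, by = 10) else numeric(0)
    got <- detect_events(s, 10, sigma = 1, params, stim_times = st)
    ref <- naive_detect(s, 10, sigma = 1, params, stim_times = st)
    expect_identical(got$onset_idx, ref$onset_idx)
    expect_identical(got$end_idx, ref$end_idx)
    expect_identical(got$peak_idx, ref$peak_idx)
    expect_identical(got$class, ref$class)
    expect_identical(got$stim_index, ref$stim_index)
  }
})

test_that("degenerate traces are rejected with a diagnostic", {
  expect_error(detect_trace(rep(5, 600), 10), "degenerate")
})
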