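test_that("projection is the pixelwise mean", {
  st <- array(2, dim = c(4, 4, 6))
  expect_equal(average_projection(st), matrix(2, 4, 4))
  st2 <- array(c(rep(1, 16), rep(3, 16)), dim = c(4, 4, 2))
  st2 <- array(rep(st2, 3), dim = c(4, 4, 6))
  expect_equal(average_projection(st2), matrix(2, 4, 4))
  expect_error(average_projection(st, integer(0)), "empty")
  expect_error(average_projection(st, 1:3), "at least 5")
})

test_that("rendering conserves punctum mass and supports 3-um ROIs", {
  tr <- rep(50, 10)
  mv <- render_movie(matrix(tr, ncol = 1), cbind(5, 5), pixel_size = 0.25,
                     psf_sigma = 0.5)
  expect_equal(dim(mv$stack)[3], 10)
  for (i in 2:10) expect_identical(mv$stack[, , i], mv$stack[, , 1])
  expect_equal(sum(mv$stack[, , 1]), 50, tolerance = 1e-6)
  # >= 95% of a psf sigma 0.5 um punctum falls inside a 3-um circle
  px <- roi_pixels(20, 20, 3, 0.25, dim_px = dim(mv$stack)[1:2])
  mv2 <- render_movie(matrix(100, 1, 1), cbind(5, 5), pixel_size = 0.25,
                      psf_sigma = 0.5)
  inroi <- sum(mv2$stack[, , 1][px])
  expect_gte(inroi / sum(mv2$stack[, , 1]), 0.95)
  expect_error(render_movie(matrix(1, 1, 2), rbind(c(2, 2), c(3, 3))),
               "closer")
  expect_error(render_movie(matrix(1, 1, 1), cbind(100, 100),
                            fov_px = c(40, 40)), "outside")
})

test_that("puncta are recovered exactly on noise-free renders", {
  centers <- cbind(x = c(3, 10, 5, 12, 8), y = c(3, 4, 10, 11, 7.5))
  mv <- render_movie(matrix(100, 5, 5, byrow = TRUE), centers,
                     pixel_size = 0.25, psf_sigma = 0.5)
  proj <- average_projection(mv$stack)
  p <- detect_puncta(proj, 0.25)
  expect_equal(nrow(p), 5) # 100% recall at >= 3 um separation
  for (i in seq_len(5)) {
    d <- sqrt((p$x_px - mv$centers_px$x_px[i])^2 +
                (p$y_px - mv$centers_px$y_px[i])^2)
    expect_lte(min(d), 1)
  }
  expect_equal(nrow(detect_puncta(matrix(0, 30, 30), 0.25)), 0)
  # two puncta 2 um apart collapse to one center (separation rule)
  mv2 <- render_movie(matrix(100, 5, 2), cbind(c(4, 6), c(4, 4)),
                      pixel_size = 0.25, psf_sigma = 0.5,
                      min_separation_um = 1.5)
  expect_equal(nrow(detect_puncta(average_projection(mv2$stack), 0.25)), 1)
})

test_that("ROI masks are circular and rotation-symmetric", {
  px <- roi_pixels(10, 10, 3, 0.25, dim_px = c(30, 30))
  dr <- px[, "row"] - 1L - 10L
  dc <- px[, "col"] - 1L - 10L
  # 90-degree rotation about the center maps the mask onto itself
  rot <- cbind(row = 10L + dc + 1L, col = 10L - dr + 1L)
  expect_setequal(paste(px[, 1], px[, 2]), paste(rot[, 1], rot[, 2]))
  expect_error(roi_pixels(1, 1, 3, 0.25, dim_px = c(30, 30)), "outside")
  expect_error(roi_pixels(10, 10, 0.5, 0.25, dim_px = c(30, 30)), "3 pixels")
})

test_that("extracted traces track the generating signal", {
  st <- array(7, dim = c(20, 20, 8))
  tr <- extract_traces(st, data.frame(x_px = 10, y_px = 10))
  expect_equal(as.numeric(tr), rep(7, 8))
  # off-ROI punctum leaves the trace flat at background
  mv <- render_movie(matrix(1000, 6, 1), cbind(10, 10), fov_px = c(80, 80),
                     pixel_size = 0.25)
  far <- extract_traces(mv$stack, data.frame(x_px = 70, y_px = 70))
  expect_lt(max(far), 1e-6)
  # with noise, ROI means correlate strongly with the generating trace
  cfg <- bouton_config(seed = 6)
  sim <- simulate_trace(cfg, schedule_evoked(6))
  mv2 <- render_movie(matrix(sim$trace$F, ncol = 1), cbind(4, 4),
                      fov_px = c(40, 40), pixel_size = 0.25, psf_sigma = 0.5,
                      photon_scale = 20, read_noise = 0.2, seed = 2)
  p <- detect_puncta(average_projection(mv2$stack), 0.25)
  tr2 <- extract_traces(mv2$stack, p[1, ])
  expect_gt(cor(tr2[, 1], sim$trace$F), 0.95)
  # permutation invariance: shuffling ROI order permutes columns only
  st3 <- array(rnorm(40 * 40 * 8), dim = c(40, 40, 8))
  rois <- data.frame(x_px = c(10, 12, 28), y_px = c(10, 28, 12))
  a <- extract_traces(st3, rois)
  b <- extract_traces(st3, rois[c(3, 1, 2), ])
  expect_equal(unname(a[, c(3, 1, 2)]), unname(b))
})
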