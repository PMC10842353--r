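#' Render an image stack of synthetic boutons
#'
#' Places each trace at a punctum center and renders frames as the sum of
#' 2-D Gaussian point-spread functions scaled by the trace value, with
#' optional Poisson photon noise and Gaussian read noise. The noise-free
#' integrated pixel mass of a punctum equals its trace value, so ROI-mean
#' readouts are proportional to the generating trace.
#'
#' Coordinates are 0-based pixel indices with the origin at the top-left
#' corner; `x` indexes columns, `y` rows.
#'
#' @param traces Numeric matrix, frames x puncta (F units), or a list of
#'   equal-length vectors.
#' @param centers_um Matrix (puncta x 2) of `(x, y)` centers in micrometers.
#'   Centers must be pairwise separated by at least `min_separation_um` and
#'   lie inside the field.
#' @param fov_px Field size `c(nx, ny)` in pixels; by default large enough to
#'   hold every punctum with a 3 sigma margin.
#' @param pixel_size Micrometers per pixel (default 0.25).
#' @param psf_sigma Gaussian PSF sigma, micrometers (default 0.5).
#' @param photon_scale Photons per fluorescence unit for the Poisson channel;
#'   `0` disables photon noise.
#' @param read_noise Gaussian read-noise SD (F units); `0` disables.
#' @param min_separation_um Minimum allowed center separation.
#' @param seed RNG seed for the noise channels.
#' @return List: `stack` (array `ny x nx x frames`), `centers_px`
#'   (`data.frame` with 0-based `x_px`, `y_px`), `pixel_size`.
#' @export
render_movie <- function(traces, centers_um, fov_px = NULL,
                         pixel_size = 0.25, psf_sigma = 0.5,
                         photon_scale = 0, read_noise = 0,
                         min_separation_um = 3, seed = 1L) {
  if (is.list(traces)) {
    traces <- do.call(cbind, lapply(traces, function(tr) {
      if (inherits(tr, "fluor_trace")) tr$F else tr
    }))
  }
  traces <- as.matrix(traces)
  centers_um <- matrix(as.numeric(centers_um), ncol = 2)
  k <- nrow(centers_um)
  if (ncol(traces) != k) stop("one trace per punctum required")
  if (k > 1) {
    dmin <- min(stats::dist(centers_um))
    if (dmin < min_separation_um) {
      stop(sprintf("punctum centers closer than %g um", min_separation_um))
    }
  }
  cpx <- centers_um / pixel_size
  margin <- ceiling(3 * psf_sigma / pixel_size)
  if (is.null(fov_px)) {
    fov_px <- c(ceiling(max(cpx[, 1])) + margin + 1,
                ceiling(max(cpx[, 2])) + margin + 1)
  }
  nx <- fov_px[1]; ny <- fov_px[2]
  if (any(cpx[, 1] < 0 | cpx[, 1] > nx - 1 | cpx[, 2] < 0 | cpx[, 2] > ny - 1)) {
    stop("punctum centers outside the field of view")
  }
  s_px <- psf_sigma / pixel_size
  xg <- 0:(nx - 1); yg <- 0:(ny - 1)
  # unit-mass footprints, pixels x puncta
  G <- vapply(seq_len(k), function(j) {
    gx <- exp(-(xg - cpx[j, 1])^2 / (2 * s_px^2))
    gy <- exp(-(yg - cpx[j, 2])^2 / (2 * s_px^2))
    fp <- outer(gy, gx) # ny x nx
    as.numeric(fp / sum(fp))
  }, numeric(ny * nx))
  signal <- G %*% t(traces) # pixels x frames
  set.seed(seed)
  if (photon_scale > 0) {
    signal <- matrix(stats::rpois(length(signal), pmax(signal, 0) * photon_scale),
                     nrow = nrow(signal)) / photon_scale
  }
  if (read_noise > 0) {
    signal <- signal + stats::rnorm(length(signal), 0, read_noise)
  }
  list(stack = array(signal, dim = c(ny, nx, ncol(signal))),
       centers_px = data.frame(x_px = cpx[, 1], y_px = cpx[, 2]),
       pixel_size = pixel_size)
}

#' Write / read an image stack as multi-page 16-bit TIFF
#'
#' Intensities are scaled into the 16-bit range by `scale` (data are stored
#' as `value / scale / 65535`; pass the same `scale` on read to recover F
#' units).
#'
#' @param stack Array `ny x nx x frames`.
#' @param path Output path.
#' @param scale F units mapped to the top of the 16-bit range.
#' @export
write_movie_tiff <- function(stack, path, scale = max(stack)) {
  frames <- lapply(seq_len(dim(stack)[3]), function(i) {
    pmin(pmax(stack[, , i] / scale, 0), 1)
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, scale = 1) {
  frames <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(frames[[1]])[1:2], length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]]
  arr * scale
}
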