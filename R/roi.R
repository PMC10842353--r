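#' Average intensity projection over a frame window
#'
#' Pixelwise mean over the given frames — the projection used to identify
#' active boutons during a high-activity (high-K+ or high-frequency
#' stimulation) epoch.
#'
#' @param stack Array `ny x nx x frames`.
#' @param frames Integer frame indices (default: all); at least 5.
#' @return Matrix `ny x nx`.
#' @export
average_projection <- function(stack, frames = NULL) {
  nf <- dim(stack)[3]
  if (is.null(frames)) frames <- seq_len(nf)
  if (length(frames) == 0) stop("empty frame window")
  if (length(frames) < 5) stop("projection window needs at least 5 frames")
  if (min(frames) < 1 || max(frames) > nf) stop("frame window outside stack")
  d <- dim(stack)
  matrix(rowMeans(matrix(stack[, , frames], nrow = d[1] * d[2])),
         nrow = d[1], ncol = d[2])
}

#' Separable Gaussian blur of an image
#' @noRd
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  h <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-h):h)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  conv1 <- function(m) { # along columns, edge-renormalized
    out <- apply(m, 2, function(v) {
      y <- stats::filter(c(rep(0, h), v, rep(0, h)), k, sides = 2)
      as.numeric(y[h + seq_along(v)])
    })
    w <- stats::filter(c(rep(0, h), rep(1, nrow(m)), rep(0, h)), k, sides = 2)
    out / as.numeric(w[h + seq_len(nrow(m))])
  }
  t(conv1(t(conv1(img))))
}

#' Detect punctum centers as thresholded local maxima
#'
#' The projection is lightly smoothed (Gaussian, sigma 1 px, to suppress
#' single-pixel noise); candidate centers are local maxima of the smoothed
#' image above `mean + k * SD`, accepted greedily in descending intensity
#' subject to a pairwise minimum separation (ties broken by row-major pixel
#' order). A flat image yields no centers.
#'
#' @param projection Matrix `ny x nx`.
#' @param pixel_size Micrometers per pixel.
#' @param min_separation_um Minimum center separation (default 3, the ROI
#'   diameter).
#' @param k Intensity threshold in SDs above the image mean (default 2).
#' @param blur_sigma_px Smoothing sigma in pixels.
#' @return `data.frame`: 0-based `x_px`, `y_px`, smoothed `value`.
#' @export
detect_puncta <- function(projection, pixel_size, min_separation_um = 3,
                          k = 2, blur_sigma_px = 1) {
  if (!all(is.finite(projection))) stop("projection must be finite")
  sm <- gaussian_blur(projection, blur_sigma_px)
  thr <- mean(sm) + k * stats::sd(sm)
  ny <- nrow(sm); nx <- ncol(sm)
  if (!is.finite(thr)) return(data.frame(x_px = numeric(0), y_px = numeric(0),
                                         value = numeric(0)))
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- sm
  is_max <- matrix(TRUE, ny, nx)
  for (dy in -1:1) {
    for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      nb <- pad[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)]
      is_max <- is_max & (sm >= nb)
    }
  }
  cand <- which(is_max & sm > thr, arr.ind = TRUE)
  if (!nrow(cand)) return(data.frame(x_px = numeric(0), y_px = numeric(0),
                                     value = numeric(0)))
  val <- sm[cand]
  rm_order <- (cand[, 1] - 1) * nx + (cand[, 2] - 1) # row-major tie-break
  o <- order(-val, rm_order)
  cand <- cand[o, , drop = FALSE]; val <- val[o]
  sep_px <- min_separation_um / pixel_size
  acc <- matrix(numeric(0), ncol = 2)
  acc_val <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(acc) == 0 ||
        min(sqrt((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2)) >= sep_px) {
      acc <- rbind(acc, p)
      acc_val <- c(acc_val, val[i])
    }
  }
  data.frame(x_px = acc[, 2] - 1, y_px = acc[, 1] - 1, value = acc_val)
}

#' Circular ROI pixel membership
#'
#' Member pixels are those whose centers lie within `diameter/2` of the ROI
#' center; 0-based pixel coordinates. The mask is symmetric under 90-degree
#' rotation about its center by construction.
#'
#' @param x_px,y_px ROI center, 0-based pixels.
#' @param diameter_um ROI diameter (default 3).
#' @param pixel_size Micrometers per pixel.
#' @param dim_px Image dimensions `c(ny, nx)`; membership outside the image
#'   is an error.
#' @return Integer matrix with columns `row`, `col` (1-based, for indexing).
#' @export
roi_pixels <- function(x_px, y_px, diameter_um = 3, pixel_size = 0.25,
                       dim_px) {
  r_px <- diameter_um / 2 / pixel_size
  if (diameter_um / pixel_size < 3) {
    stop("ROI diameter must span at least 3 pixels")
  }
  cols <- floor(x_px - r_px):ceiling(x_px + r_px)
  rows <- floor(y_px - r_px):ceiling(y_px + r_px)
  grid <- expand.grid(row = rows, col = cols)
  inside <- (grid$col - x_px)^2 + (grid$row - y_px)^2 <= r_px^2
  grid <- grid[inside, , drop = FALSE]
  if (any(grid$row < 0 | grid$row >= dim_px[1] |
          grid$col < 0 | grid$col >= dim_px[2])) {
    stop("ROI extends outside the image")
  }
  cbind(row = grid$row + 1L, col = grid$col + 1L)
}

#' Extract ROI-mean traces from an image stack
#'
#' Trace value = mean intensity over the ROI's member pixels, per frame.
#'
#' @param stack Array `ny x nx x frames`.
#' @param rois `data.frame` with 0-based `x_px`, `y_px` (e.g. from
#'   [detect_puncta()]).
#' @param diameter_um ROI diameter.
#' @param pixel_size Micrometers per pixel.
#' @return Numeric matrix, frames x ROIs.
#' @export
extract_traces <- function(stack, rois, diameter_um = 3, pixel_size = 0.25) {
  d <- dim(stack)
  flat <- matrix(stack, nrow = d[1] * d[2])
  out <- vapply(seq_len(nrow(rois)), function(i) {
    px <- roi_pixels(rois$x_px[i], rois$y_px[i], diameter_um, pixel_size,
                     dim_px = d[1:2])
    lin <- (px[, "col"] - 1L) * d[1] + px[, "row"]
    if (length(lin) == 1) flat[lin, ] else colMeans(flat[lin, , drop = FALSE])
  }, numeric(d[3]))
  colnames(out) <- rois$roi %||% seq_len(nrow(rois))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
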