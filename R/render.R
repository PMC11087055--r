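# Rendering tracer ensembles into synthetic fluorescence movies.

#' Imaging parameters for the synthetic microscope
#'
#' @param pixel_size um per pixel.
#' @param frame_interval seconds between frames (the movies are recorded
#'   every 3 min, i.e. 180 s).
#' @param frame_count number of frames.
#' @param image_shape `c(rows, cols)` in pixels.
#' @param spot_sigma Gaussian spot standard deviation (px).
#' @param spot_amplitude peak intensity of one spot (16-bit counts).
#' @param background_level additive background (counts).
#' @param noise_model `"none"`, `"gaussian"`, or `"poisson-gaussian"`.
#' @param noise_sd Gaussian read-noise standard deviation (counts).
#' @param bit_depth intensity clip at `2^bit_depth - 1`.
#' @return an object of class `imaging_params`.
#' @export
imaging_params <- function(pixel_size = 3.25, frame_interval = 180,
                           frame_count = 200, image_shape = c(1024L, 1024L),
                           spot_sigma = 2, spot_amplitude = 8000,
                           background_level = 400,
                           noise_model = c("gaussian", "poisson-gaussian",
                                           "none"),
                           noise_sd = 60, bit_depth = 16) {
  noise_model <- match.arg(noise_model)
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  stopifnot_scalar_pos(frame_interval, "frame_interval")
  stopifnot_scalar_pos(frame_count, "frame_count")
  structure(
    list(pixel_size = pixel_size, frame_interval = frame_interval,
         frame_count = as.integer(frame_count),
         image_shape = as.integer(image_shape), spot_sigma = spot_sigma,
         spot_amplitude = spot_amplitude,
         background_level = background_level, noise_model = noise_model,
         noise_sd = noise_sd, bit_depth = bit_depth),
    class = "imaging_params")
}

# Physical (um, y-up, origin at image center) -> pixel coordinates
# (col, row), 1-based pixel centers. Row 1 is the top image row.
um_to_px <- function(xy, shape, pixel_size) {
  cbind(col = xy[, 1] / pixel_size + (shape[2] + 1) / 2,
        row = (shape[1] + 1) / 2 - xy[, 2] / pixel_size)
}

# Inverse of um_to_px for grid coordinates.
px_to_um_x <- function(col, shape, pixel_size) (col - (shape[2] + 1) / 2) * pixel_size
px_to_um_y <- function(row, shape, pixel_size) ((shape[1] + 1) / 2 - row) * pixel_size

#' Render Gaussian spots onto a single image
#'
#' Draws isotropic Gaussian spots at the given pixel positions on a flat
#' background. No noise is added here. Spots whose center falls outside
#' the image bounds are silently omitted.
#'
#' @param positions_px n x 2 matrix of spot centers, columns `(col, row)`
#'   in pixels (1-based pixel centers).
#' @param shape `c(rows, cols)`.
#' @param sigma spot standard deviation (px).
#' @param amplitude peak spot intensity.
#' @param background additive constant background.
#' @return a `rows x cols` numeric matrix.
#' @export
render_spots <- function(positions_px, shape, sigma = 2, amplitude = 1,
                         background = 0) {
  nr <- shape[1]; nc <- shape[2]
  img <- matrix(background, nr, nc)
  if (is.null(dim(positions_px))) positions_px <- matrix(positions_px, ncol = 2)
  if (nrow(positions_px) == 0L) return(img)
  cx <- positions_px[, 1]; cy <- positions_px[, 2]
  keep <- cx >= 1 & cx <= nc & cy >= 1 & cy <= nr
  cx <- cx[keep]; cy <- cy[keep]
  n <- length(cx)
  if (n == 0L) return(img)
  rad <- ceiling(3 * sigma)
  off <- seq(-rad, rad)
  m <- length(off)
  # patch pixel coordinates for every particle (n x m each axis)
  px <- outer(round(cx), off, "+")
  py <- outer(round(cy), off, "+")
  # weights: separable Gaussian evaluated at pixel centers
  wx <- exp(-(px - cx)^2 / (2 * sigma^2))
  wy <- exp(-(py - cy)^2 / (2 * sigma^2))
  # expand to full patches: rows index particles
  idx_r <- py[, rep(seq_len(m), each = m)]
  idx_c <- px[, rep(seq_len(m), times = m)]
  w <- amplitude * wy[, rep(seq_len(m), each = m)] *
    wx[, rep(seq_len(m), times = m)]
  ok <- idx_r >= 1 & idx_r <= nr & idx_c >= 1 & idx_c <= nc
  lin <- as.integer((idx_c[ok] - 1L) * nr + idx_r[ok])
  acc <- group_sum(w[ok], lin)
  img[acc$index] <- img[acc$index] + acc$sum
  img
}

#' Render a tracer ensemble into a time-lapse image stack
#'
#' Each particle is drawn as an isotropic Gaussian spot; background and
#' per-pixel noise are added per the imaging parameters; intensities are
#' clipped to the declared bit depth. The image is centered on the origin
#' of the ensemble's physical coordinates, with image rows increasing
#' toward negative y (microscopy convention).
#'
#' @param ensemble a [advect_particles()] result (times must align with
#'   `frame_interval * (0:(frame_count-1))`).
#' @param params an [imaging_params()].
#' @param seed integer seed for the noise; rendering is deterministic
#'   given `seed`.
#' @return an object of class `image_stack`: list of frames (matrices),
#'   plus `pixel_size`, `frame_interval`, `times`.
#' @export
render_frames <- function(ensemble, params, seed = 1L) {
  stopifnot(inherits(ensemble, "particle_ensemble"),
            inherits(params, "imaging_params"))
  nt <- length(ensemble$times)
  expect_t <- params$frame_interval * (seq_len(nt) - 1)
  if (max(abs(ensemble$times - ensemble$times[1] - expect_t)) >
      1e-6 * params$frame_interval) {
    stop("ensemble times do not align with frame_interval x frame index",
         call. = FALSE)
  }
  shape <- params$image_shape
  clip <- 2^params$bit_depth - 1
  frames <- with_seed(seed, {
    lapply(seq_len(nt), function(k) {
      pos_um <- matrix(ensemble$positions[, , k], ncol = 2L)
      pos_px <- um_to_px(pos_um, shape, params$pixel_size)
      img <- render_spots(pos_px, shape, sigma = params$spot_sigma,
                          amplitude = params$spot_amplitude,
                          background = params$background_level)
      img <- switch(params$noise_model,
        none = img,
        gaussian = img + matrix(stats::rnorm(length(img), 0, params$noise_sd),
                                nrow(img)),
        `poisson-gaussian` = {
          matrix(stats::rpois(length(img), lambda = pmax(img, 0)), nrow(img)) +
            matrix(stats::rnorm(length(img), 0, params$noise_sd), nrow(img))
        })
      pmin(pmax(img, 0), clip)
    })
  })
  structure(list(frames = frames, pixel_size = params$pixel_size,
                 frame_interval = params$frame_interval,
                 times = ensemble$times),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames of %d x %d px (%.2f um/px, %g s/frame)\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' @param stack an `image_stack`.
#' @param path output path.
#' @param bit_depth bit depth used for scaling (default 16).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, bit_depth = 16) {
  stopifnot(inherits(stack, "image_stack"))
  clip <- 2^bit_depth - 1
  pages <- lapply(stack$frames, function(f) pmin(pmax(f / clip, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file path.
#' @param pixel_size um per pixel.
#' @param frame_interval seconds per frame.
#' @param bit_depth bit depth used to rescale intensities back to counts.
#' @return an `image_stack`.
#' @export
read_image_stack <- function(path, pixel_size = 3.25, frame_interval = 180,
                             bit_depth = 16) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  clip <- 2^bit_depth - 1
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    p * clip
  })
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 times = frame_interval * (seq_along(frames) - 1)),
            class = "image_stack")
}
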