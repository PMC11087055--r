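# Gridded velocity fields: container, conversions, text I/O, plotting.

#' Construct a gridded velocity field
#'
#' Matrices are laid out with rows indexing `y` (ascending) and columns
#' indexing `x` (ascending). Pixel-unit fields produced by the PIV engine
#' use image coordinates (y = row index, increasing downward);
#' calibrated physical fields use y-up coordinates.
#'
#' @param x,y ascending grid node coordinates (px or um).
#' @param u,v velocity components (matrices, `length(y)` x `length(x)`);
#'   `u` is along +x, `v` along +y of the stated coordinate frame.
#' @param valid logical matrix: node carries a measured (or accepted)
#'   vector.
#' @param interpolated logical matrix: node value was filled from
#'   neighbors rather than measured.
#' @param units `"px_per_frame"` or `"um_per_s"`.
#' @param t timestamp (s).
#' @return an object of class `velocity_field`.
#' @export
velocity_field <- function(x, y, u, v, valid = NULL, interpolated = NULL,
                           units = c("px_per_frame", "um_per_s"), t = 0) {
  units <- match.arg(units)
  u <- as.matrix(u); v <- as.matrix(v)
  ny <- length(y); nx <- length(x)
  if (!all(dim(u) == c(ny, nx)) || !all(dim(v) == c(ny, nx))) {
    stop("`u` and `v` must be length(y) x length(x) matrices", call. = FALSE)
  }
  if (is.null(valid)) valid <- matrix(TRUE, ny, nx)
  if (is.null(interpolated)) interpolated <- matrix(FALSE, ny, nx)
  if (!all(dim(valid) == dim(u)) || !all(dim(interpolated) == dim(u))) {
    stop("`valid`/`interpolated` must be congruent with `u`", call. = FALSE)
  }
  if (ny > 1 && any(diff(y) <= 0)) stop("`y` must be ascending", call. = FALSE)
  if (nx > 1 && any(diff(x) <= 0)) stop("`x` must be ascending", call. = FALSE)
  structure(list(x = as.numeric(x), y = as.numeric(y), u = u, v = v,
                 valid = valid, interpolated = interpolated,
                 units = units, t = t),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  spd <- sqrt(x$u^2 + x$v^2)
  cat(sprintf(paste0("<velocity_field> %d x %d nodes, units %s, t = %g s\n",
                     "  valid %.0f%%, interpolated %.0f%%, max |v| = %.4g\n"),
              length(x$y), length(x$x), x$units, x$t,
              100 * mean(x$valid), 100 * mean(x$interpolated),
              max(spd[x$valid], 0)))
  invisible(x)
}

grid_spacing <- function(field) {
  dx <- if (length(field$x) > 1) diff(field$x)[1] else 1
  dy <- if (length(field$y) > 1) diff(field$y)[1] else 1
  c(dx = dx, dy = dy)
}

#' Calibrate a pixel-unit field into physical units
#'
#' Multiplies velocities by `pixel_size / frame_interval` and grid
#' coordinates by `pixel_size`, and re-tags the units as `um_per_s`.
#' Attempting to calibrate an already calibrated field is an error.
#'
#' @param field a `velocity_field` in `px_per_frame` units.
#' @param pixel_size um per pixel (> 0).
#' @param frame_interval seconds per frame (> 0).
#' @return the calibrated `velocity_field`.
#' @export
calibrate <- function(field, pixel_size, frame_interval) {
  stopifnot(inherits(field, "velocity_field"))
  if (field$units != "px_per_frame") {
    stop("field is already calibrated (units are not px_per_frame)",
         call. = FALSE)
  }
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  stopifnot_scalar_pos(frame_interval, "frame_interval")
  s <- pixel_size / frame_interval
  velocity_field(field$x * pixel_size, field$y * pixel_size,
                 field$u * s, field$v * s,
                 valid = field$valid, interpolated = field$interpolated,
                 units = "um_per_s", t = field$t)
}

#' Convert an image-coordinate PIV field to physical y-up coordinates
#'
#' Calibrates, re-centers the grid on the image center, flips the y axis
#' (image rows increase downward; physical y increases upward, anterior
#' up) and negates the v component accordingly.
#'
#' @param field `velocity_field` in `px_per_frame`, image coordinates.
#' @param image_shape `c(rows, cols)` of the source images (px).
#' @param pixel_size um per pixel.
#' @param frame_interval seconds per frame.
#' @return a calibrated `velocity_field` in physical coordinates.
#' @export
as_physical_field <- function(field, image_shape, pixel_size, frame_interval) {
  cal <- calibrate(field, pixel_size, frame_interval)
  ny <- length(cal$y)
  flip <- rev(seq_len(ny))
  x_um <- px_to_um_x(field$x, image_shape, pixel_size)
  y_um <- rev(px_to_um_y(field$y, image_shape, pixel_size))
  velocity_field(x_um, y_um,
                 u = cal$u[flip, , drop = FALSE],
                 v = -cal$v[flip, , drop = FALSE],
                 valid = cal$valid[flip, , drop = FALSE],
                 interpolated = cal$interpolated[flip, , drop = FALSE],
                 units = "um_per_s", t = field$t)
}

#' Write a velocity field as delimited text
#'
#' Long format with header `x,y,u,v,valid,interpolated`; a JSON sidecar
#' (same path + `.json`) records units, timestamp and any extra metadata.
#'
#' @param field a `velocity_field`.
#' @param path output file path (CSV).
#' @param meta optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_velocity_field <- function(field, path, meta = list()) {
  stopifnot(inherits(field, "velocity_field"))
  df <- data.frame(
    x = rep(field$x, each = length(field$y)),
    y = rep(field$y, times = length(field$x)),
    u = as.vector(field$u), v = as.vector(field$v),
    valid = as.integer(as.vector(field$valid)),
    interpolated = as.integer(as.vector(field$interpolated)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- c(list(units = field$units, t = field$t,
                    nx = length(field$x), ny = length(field$y)), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a velocity field written by [write_velocity_field()]
#'
#' @param path CSV path (with its `.json` sidecar alongside).
#' @return a `velocity_field`.
#' @export
read_velocity_field <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  x <- sort(unique(df$x)); y <- sort(unique(df$y))
  ny <- length(y); nx <- length(x)
  ix <- match(df$x, x); iy <- match(df$y, y)
  mk <- function(col, default = NA_real_) {
    m <- matrix(default, ny, nx)
    m[cbind(iy, ix)] <- col
    m
  }
  velocity_field(x, y, mk(df$u), mk(df$v),
                 valid = mk(df$valid, 0) > 0,
                 interpolated = mk(df$interpolated, 0) > 0,
                 units = side$units, t = side$t)
}

#' Quiver plot of a velocity field
#'
#' @param x a `velocity_field`.
#' @param scale arrow length multiplier (plot units per velocity unit);
#'   `NULL` picks a scale from the grid spacing and speed range.
#' @param ... passed to [graphics::arrows()].
#' @return `x`, invisibly.
#' @export
plot.velocity_field <- function(x, scale = NULL, ...) {
  sp <- grid_spacing(x)
  spd <- sqrt(x$u^2 + x$v^2)
  if (is.null(scale)) {
    mx <- max(spd[x$valid], na.rm = TRUE)
    scale <- if (mx > 0) 0.9 * min(abs(sp)) / mx else 1
  }
  X <- rep(x$x, each = length(x$y)); Y <- rep(x$y, times = length(x$x))
  U <- as.vector(x$u) * scale; V <- as.vector(x$v) * scale
  ok <- as.vector(x$valid) & (abs(U) + abs(V)) > 0
  graphics::plot(range(x$x), range(x$y), type = "n", asp = 1,
                 xlab = "x", ylab = "y",
                 main = sprintf("velocity field (%s)", x$units))
  graphics::arrows(X[ok], Y[ok], X[ok] + U[ok], Y[ok] + V[ok],
                   length = 0.03, ...)
  invisible(x)
}
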