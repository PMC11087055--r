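# Derived fields: time averages, vorticity/divergence, streamlines, and
# trajectory projections.

#' Time-ordered series of velocity fields
#'
#' All fields must share the same grid and units; timestamps must be
#' strictly increasing. `t0_offset` records the time of flow initiation
#' (analyses report times relative to it).
#'
#' @param fields list of `velocity_field`s.
#' @param t0_offset initiation time (s), default 0.
#' @return an object of class `field_series`.
#' @export
field_series <- function(fields, t0_offset = 0) {
  if (!length(fields) || !all(vapply(fields, inherits, logical(1),
                                     "velocity_field"))) {
    stop("`fields` must be a non-empty list of velocity_field", call. = FALSE)
  }
  f1 <- fields[[1]]
  for (f in fields[-1]) {
    if (!identical(f$units, f1$units) ||
        length(f$x) != length(f1$x) || length(f$y) != length(f1$y) ||
        max(abs(f$x - f1$x)) > 1e-9 || max(abs(f$y - f1$y)) > 1e-9) {
      stop("all fields must share grid and units", call. = FALSE)
    }
  }
  ts <- vapply(fields, function(f) f$t, numeric(1))
  if (length(ts) > 1 && any(diff(ts) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  structure(list(fields = fields, times = ts, t0_offset = t0_offset),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("<field_series> %d fields, t = %g..%g s (%s)\n",
              length(x$fields), min(x$times), max(x$times),
              x$fields[[1]]$units))
  invisible(x)
}

#' Time-average a velocity-field series
#'
#' Per-node mean of u and v over the frames whose timestamp lies in
#' `[t_start, t_end]`, counting only nodes valid in each frame. A node is
#' valid in the output iff it was valid in at least half of the averaged
#' frames.
#'
#' @param series a [field_series()].
#' @param t_start,t_end averaging interval (s, inclusive).
#' @return a `velocity_field` with `t` set to the interval midpoint.
#' @export
time_average <- function(series, t_start, t_end) {
  stopifnot(inherits(series, "field_series"))
  sel <- which(series$times >= t_start & series$times <= t_end)
  if (!length(sel)) stop("no fields in the averaging interval", call. = FALSE)
  f1 <- series$fields[[1]]
  ny <- length(f1$y); nx <- length(f1$x)
  su <- sv <- nv <- matrix(0, ny, nx)
  for (i in sel) {
    f <- series$fields[[i]]
    m <- f$valid
    su <- su + ifelse(m, f$u, 0)
    sv <- sv + ifelse(m, f$v, 0)
    nv <- nv + m
  }
  u <- ifelse(nv > 0, su / pmax(nv, 1), 0)
  v <- ifelse(nv > 0, sv / pmax(nv, 1), 0)
  velocity_field(f1$x, f1$y, u, v, valid = nv >= length(sel) / 2,
                 units = f1$units, t = mean(c(t_start, t_end)))
}

# Central-difference partials of a scalar matrix on a regular grid,
# one-sided at the borders. Returns list(d_dx, d_dy, ok) where ok marks
# nodes whose stencil used only valid neighbors.
grid_partials <- function(z, valid, dx, dy) {
  ny <- nrow(z); nx <- ncol(z)
  if (ny < 3L || nx < 3L) stop("grid must be at least 3x3", call. = FALSE)
  ddx <- matrix(NA_real_, ny, nx)
  ddy <- matrix(NA_real_, ny, nx)
  okx <- oky <- matrix(FALSE, ny, nx)
  # x: columns
  ddx[, 2:(nx - 1)] <- (z[, 3:nx] - z[, 1:(nx - 2)]) / (2 * dx)
  okx[, 2:(nx - 1)] <- valid[, 3:nx] & valid[, 1:(nx - 2)]
  ddx[, 1] <- (z[, 2] - z[, 1]) / dx
  ddx[, nx] <- (z[, nx] - z[, nx - 1]) / dx
  okx[, 1] <- valid[, 1] & valid[, 2]
  okx[, nx] <- valid[, nx] & valid[, nx - 1]
  # y: rows
  ddy[2:(ny - 1), ] <- (z[3:ny, ] - z[1:(ny - 2), ]) / (2 * dy)
  oky[2:(ny - 1), ] <- valid[3:ny, ] & valid[1:(ny - 2), ]
  ddy[1, ] <- (z[2, ] - z[1, ]) / dy
  ddy[ny, ] <- (z[ny, ] - z[ny - 1, ]) / dy
  oky[1, ] <- valid[1, ] & valid[2, ]
  oky[ny, ] <- valid[ny, ] & valid[ny - 1, ]
  list(d_dx = ddx, d_dy = ddy, ok = okx & oky)
}

scalar_field <- function(x, y, values, valid, kind, t = 0) {
  structure(list(x = x, y = y, values = values, valid = valid,
                 kind = kind, t = t),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  rng <- range(x$values[x$valid], na.rm = TRUE)
  cat(sprintf("<scalar_field> %s, %d x %d nodes, range [%.3g, %.3g]\n",
              x$kind, length(x$y), length(x$x), rng[1], rng[2]))
  invisible(x)
}

#' Vorticity of a velocity field
#'
#' Computes \eqn{\omega = \partial v/\partial x - \partial u/\partial y}
#' by central differences (one-sided at the border ring). In the y-up
#' physical frame, positive vorticity is counter-clockwise rotation; the
#' magnitude of the vorticity is twice the local angular velocity.
#' Derivatives that would use an invalid neighbor are marked invalid.
#'
#' @param field a calibrated `velocity_field` (units `um_per_s`).
#' @return a `scalar_field` of kind `"vorticity"` (1/s).
#' @export
vorticity <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  if (field$units != "um_per_s") {
    stop("vorticity expects a calibrated field (um_per_s)", call. = FALSE)
  }
  sp <- grid_spacing(field)
  dv <- grid_partials(field$v, field$valid, sp["dx"], sp["dy"])
  du <- grid_partials(field$u, field$valid, sp["dx"], sp["dy"])
  scalar_field(field$x, field$y, dv$d_dx - du$d_dy,
               valid = dv$ok & du$ok & field$valid,
               kind = "vorticity", t = field$t)
}

#' Divergence of a velocity field
#'
#' \eqn{\partial u/\partial x + \partial v/\partial y} by central
#' differences; a quality-control companion to [vorticity()] (the
#' epiblast flows analyzed here should be nearly divergence-free).
#'
#' @param field a calibrated `velocity_field`.
#' @return a `scalar_field` of kind `"divergence"` (1/s).
#' @export
divergence <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  if (field$units != "um_per_s") {
    stop("divergence expects a calibrated field (um_per_s)", call. = FALSE)
  }
  sp <- grid_spacing(field)
  du <- grid_partials(field$u, field$valid, sp["dx"], sp["dy"])
  dv <- grid_partials(field$v, field$valid, sp["dx"], sp["dy"])
  scalar_field(field$x, field$y, du$d_dx + dv$d_dy,
               valid = du$ok & dv$ok & field$valid,
               kind = "divergence", t = field$t)
}

#' Write a scalar field as delimited text
#'
#' Long format with header `x,y,value,valid`.
#'
#' @param sf a `scalar_field`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scalar_field <- function(sf, path) {
  df <- data.frame(x = rep(sf$x, each = length(sf$y)),
                   y = rep(sf$y, times = length(sf$x)),
                   value = as.vector(sf$values),
                   valid = as.integer(as.vector(sf$valid)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Integrate streamlines of a velocity field
#'
#' Classical 4th-order integration of the normalized direction field with
#' bilinear interpolation between nodes. Each line is advanced in steps of
#' `step` until it leaves the grid hull, stagnates (speed below `v_floor`),
#' closes (returns within `step` of its start after at least 10 steps), or
#' reaches `max_steps`.
#'
#' @param field a `velocity_field`.
#' @param seeds n x 2 matrix of seed points (grid units); `NULL` seeds a
#'   uniform grid at 4x the field grid spacing.
#' @param step integration step (grid units); default half the grid
#'   spacing.
#' @param max_steps maximum number of steps per line.
#' @param v_floor stagnation speed floor (fraction of the field's max
#'   speed).
#' @return an object of class `streamline_set`: list of polylines
#'   (matrices), seed points, step, and per-line termination reasons
#'   (`"exit"`, `"stagnation"`, `"closed"`, `"max_steps"`).
#' @export
streamlines <- function(field, seeds = NULL, step = NULL, max_steps = 2000L,
                        v_floor = 1e-3) {
  stopifnot(inherits(field, "velocity_field"))
  sp <- grid_spacing(field)
  if (is.null(step)) step <- min(abs(sp)) / 2
  if (is.null(seeds)) {
    sx <- seq(min(field$x), max(field$x), by = 4 * abs(sp["dx"]))
    sy <- seq(min(field$y), max(field$y), by = 4 * abs(sp["dy"]))
    seeds <- cbind(rep(sx, each = length(sy)), rep(sy, times = length(sx)))
  }
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 2)
  xr <- range(field$x); yr <- range(field$y)
  inside <- seeds[, 1] >= xr[1] & seeds[, 1] <= xr[2] &
    seeds[, 2] >= yr[1] & seeds[, 2] <= yr[2]
  if (!all(inside)) stop("all seeds must lie inside the grid hull",
                         call. = FALSE)
  vmax <- max(sqrt(field$u^2 + field$v^2)[field$valid], 0)
  floor_abs <- v_floor * vmax

  dir_at <- function(p) {
    u <- bilinear(field$x, field$y, field$u, p[1], p[2])
    v <- bilinear(field$x, field$y, field$v, p[1], p[2])
    m <- sqrt(u * u + v * v)
    if (!is.finite(m) || m <= floor_abs) return(NULL)
    c(u, v) / m
  }
  in_hull <- function(p) {
    p[1] >= xr[1] && p[1] <= xr[2] && p[2] >= yr[1] && p[2] <= yr[2]
  }

  lines <- vector("list", nrow(seeds))
  reasons <- character(nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    p <- seeds[i, ]
    pts <- matrix(p, ncol = 2)
    reason <- "max_steps"
    for (k in seq_len(max_steps)) {
      d1 <- dir_at(p)
      if (is.null(d1)) { reason <- "stagnation"; break }
      d2 <- dir_at(p + step / 2 * d1)
      d3 <- if (!is.null(d2)) dir_at(p + step / 2 * d2) else NULL
      d4 <- if (!is.null(d3)) dir_at(p + step * d3) else NULL
      if (is.null(d2) || is.null(d3) || is.null(d4)) {
        reason <- "stagnation"; break
      }
      pn <- p + step / 6 * (d1 + 2 * d2 + 2 * d3 + d4)
      if (!in_hull(pn)) { reason <- "exit"; break }
      pts <- rbind(pts, pn)
      p <- pn
      if (k >= 10L && sqrt(sum((p - seeds[i, ])^2)) < step) {
        reason <- "closed"; break
      }
    }
    lines[[i]] <- pts
    reasons[i] <- reason
  }
  structure(list(polylines = lines, seed_points = seeds, step_length = step,
                 reasons = reasons),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d lines (%s)\n", length(x$polylines),
              paste(sprintf("%s: %d", names(table(x$reasons)),
                            table(x$reasons)), collapse = ", ")))
  invisible(x)
}

#' Write streamlines as delimited text
#'
#' Long format with header `line_id,point_index,x,y`.
#'
#' @param sl a `streamline_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(sl, path) {
  n <- vapply(sl$polylines, nrow, integer(1))
  df <- data.frame(
    line_id = rep(seq_along(sl$polylines), times = n),
    point_index = unlist(lapply(n, seq_len)),
    x = unlist(lapply(sl$polylines, function(m) m[, 1])),
    y = unlist(lapply(sl$polylines, function(m) m[, 2])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trajectory projections of an image stack (Flowtrace-style)
#'
#' Sliding-window projection of consecutive frames, visualizing particle
#' trajectories as streaks. `mode = "max"` returns plain maximum-intensity
#' projections; `mode = "time-coded"` additionally encodes time within the
#' window: the output has a second channel weighted toward the most recent
#' frames, so trajectories run from green (past) to yellow (present) when
#' the two channels are displayed as G and R+G.
#'
#' Note that streak projections trace actual particle paths; for unsteady
#' flow they need not coincide with instantaneous streamlines.
#'
#' @param stack an `image_stack`.
#' @param window_frames frames per projection window (2 to frame count);
#'   30-minute windows at 3-minute sampling correspond to 10 frames.
#' @param mode `"max"` or `"time-coded"`.
#' @return a list of projections (stride 1: `frame_count - window_frames +
#'   1` outputs); each is a matrix (`max`) or rows x cols x 2 array
#'   (`time-coded`, channels = max projection, recency-weighted max).
#' @export
flowtrace_projection <- function(stack, window_frames = 10L,
                                 mode = c("max", "time-coded")) {
  stopifnot(inherits(stack, "image_stack"))
  mode <- match.arg(mode)
  nt <- length(stack$frames)
  if (window_frames < 2L || window_frames > nt) {
    stop("`window_frames` must be in [2, frame_count]", call. = FALSE)
  }
  n_out <- nt - window_frames + 1L
  wts <- seq(0, 1, length.out = window_frames)
  out <- vector("list", n_out)
  for (s in seq_len(n_out)) {
    idx <- s:(s + window_frames - 1L)
    mx <- stack$frames[[idx[1]]]
    if (mode == "time-coded") rc <- wts[1] * stack$frames[[idx[1]]]
    for (j in seq_along(idx)[-1]) {
      f <- stack$frames[[idx[j]]]
      mx <- pmax(mx, f)
      if (mode == "time-coded") rc <- pmax(rc, wts[j] * f)
    }
    out[[s]] <- if (mode == "max") mx else {
      a <- array(0, dim = c(dim(mx), 2L)); a[, , 1] <- mx; a[, , 2] <- rc; a
    }
  }
  out
}
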