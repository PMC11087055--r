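# Tracer advection through an analytic flow model.

#' Advect tracer particles through a flow model
#'
#' Integrates particle trajectories with a classical 4th-order Runge-Kutta
#' step per frame interval. Because the model velocity is exactly zero at
#' and outside the disc edge, particles cannot leave the disc.
#'
#' @param model a [flow_model()].
#' @param initial_positions n x 2 matrix of starting positions (um),
#'   inside the disc.
#' @param times strictly increasing, uniformly spaced times (s).
#' @return an object of class `particle_ensemble`: list with `ids`,
#'   `times`, and `positions`, an `n x 2 x length(times)` array (um).
#' @export
advect_particles <- function(model, initial_positions, times) {
  stopifnot(inherits(model, "flow_model"))
  if (is.null(dim(initial_positions))) {
    initial_positions <- matrix(initial_positions, ncol = 2)
  }
  pos <- as.matrix(initial_positions)
  if (!all(is.finite(pos))) stop("non-finite initial positions", call. = FALSE)
  nt <- length(times)
  if (nt < 1L) stop("`times` must be non-empty", call. = FALSE)
  dts <- diff(times)
  if (nt > 1L) {
    if (any(dts <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
    if (max(abs(dts - dts[1])) > 1e-6 * dts[1]) {
      stop("`times` must be uniformly spaced", call. = FALSE)
    }
  }
  rr <- sqrt((pos[, 1] - model$disc_center[1])^2 +
             (pos[, 2] - model$disc_center[2])^2)
  if (any(rr > model$disc_radius)) {
    stop("initial positions must lie inside the disc", call. = FALSE)
  }

  n <- nrow(pos)
  out <- array(NA_real_, dim = c(n, 2L, nt))
  out[, , 1L] <- pos
  max_step <- 0
  for (k in seq_len(nt - 1L)) {
    t0 <- times[k]; dt <- dts[k]
    k1 <- velocity_at(model, pos, t0)
    k2 <- velocity_at(model, pos + dt / 2 * k1, t0 + dt / 2)
    k3 <- velocity_at(model, pos + dt / 2 * k2, t0 + dt / 2)
    k4 <- velocity_at(model, pos + dt * k3, t0 + dt)
    step <- dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    pos <- pos + step
    out[, , k + 1L] <- pos
    max_step <- max(max_step, sqrt(max(rowSums(step^2))))
  }
  min_core <- min(vapply(c(model$primary_pair, model$secondary_pair),
                         function(v) v$core_radius, numeric(1)))
  if (nt > 1L && max_step > min_core) {
    warning(sprintf(paste0("largest per-step displacement (%.1f um) exceeds ",
                           "the smallest core radius (%.1f um); integration ",
                           "accuracy may suffer"), max_step, min_core),
            call. = FALSE)
  }
  structure(list(ids = seq_len(n), times = times, positions = out),
            class = "particle_ensemble")
}

#' @export
print.particle_ensemble <- function(x, ...) {
  cat(sprintf("<particle_ensemble> %d particles x %d time points (%.2f h)\n",
              length(x$ids), length(x$times),
              diff(range(x$times)) / 3600))
  invisible(x)
}

#' Write ground-truth trajectories as delimited text
#'
#' Long format with header `id,t_s,x_um,y_um`.
#'
#' @param ensemble a [advect_particles()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  nt <- length(ensemble$times)
  n <- length(ensemble$ids)
  df <- data.frame(
    id = rep(ensemble$ids, times = nt),
    t_s = rep(ensemble$times, each = n),
    x_um = as.vector(ensemble$positions[, 1L, ]),
    y_um = as.vector(ensemble$positions[, 2L, ]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
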