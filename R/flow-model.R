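# Analytic ground-truth flow models: counter-rotating vortex pairs on an
# embryonic disc, with time-dependent amplitude envelopes.

# Lamb-Oseen shape constant: the azimuthal speed (1 - exp(-A s^2))/s peaks
# at s = 1 when A = 1.25643...
LAMB_OSEEN_ALPHA <- 1.2564312086261697
LAMB_OSEEN_PEAK <- 1 - exp(-LAMB_OSEEN_ALPHA)

#' Specify a single vortex
#'
#' A finite-core vortex with a Lamb-Oseen-style azimuthal speed profile
#' \eqn{u_\theta(r) \propto (1 - e^{-\alpha r^2/r_c^2})/r}, scaled so the
#' maximum speed (attained at \eqn{r = r_c}) equals `peak_speed`.
#'
#' @param center numeric length-2, core position in disc coordinates (um).
#' @param circulation_sign `+1` (counter-clockwise) or `-1` (clockwise),
#'   in y-up physical coordinates.
#' @param peak_speed maximum azimuthal speed (um/s), `>= 0`.
#' @param core_radius radius of peak azimuthal speed (um), `> 0`.
#' @return an object of class `vortex_spec`.
#' @export
#' @examples
#' vortex_spec(c(-430, 0), +1, peak_speed = 0.2, core_radius = 300)
vortex_spec <- function(center, circulation_sign, peak_speed, core_radius) {
  if (length(center) != 2L || !all(is.finite(center))) {
    stop("`center` must be a finite length-2 position", call. = FALSE)
  }
  if (!circulation_sign %in% c(-1, 1)) {
    stop("`circulation_sign` must be +1 or -1", call. = FALSE)
  }
  if (!is.numeric(peak_speed) || peak_speed < 0) {
    stop("`peak_speed` must be >= 0", call. = FALSE)
  }
  stopifnot_scalar_pos(core_radius, "core_radius")
  structure(
    list(center = as.numeric(center),
         circulation_sign = as.numeric(circulation_sign),
         peak_speed = as.numeric(peak_speed),
         core_radius = as.numeric(core_radius)),
    class = "vortex_spec")
}

#' Time-dependent amplitude envelope
#'
#' Modulates the strength of a vortex pair over the movie. All kinds map
#' time (s) to a dimensionless amplitude in \[0, 1\]:
#' \describe{
#'   \item{constant}{always 1.}
#'   \item{ramp}{smoothstep from 0 at `t_on` to 1 at `t_on + t_ramp`, then
#'     holds (a flow that strengthens over time, then persists).}
#'   \item{ramp_then_decay}{as `ramp`, then a cosine ramp down to `floor`
#'     over the window `[t_decay - decay_width, t_decay]`; the flow has
#'     ceased (amplitude = `floor`) at `t_decay`.}
#'   \item{crossfade}{smoothstep from 0 starting at `t_on` over `t_ramp`
#'     (a pair that switches on later, e.g. along an induced axis).}
#' }
#'
#' @param kind one of `"constant"`, `"ramp"`, `"ramp_then_decay"`,
#'   `"crossfade"`.
#' @param t_ramp ramp-up duration (s).
#' @param t_decay center of the decay window (s), for `ramp_then_decay`.
#' @param decay_width full width of the decay window (s).
#' @param floor residual amplitude after decay, in \[0, 1\].
#' @param t_on onset time (s).
#' @return an object of class `amplitude_envelope`.
#' @export
amplitude_envelope <- function(kind = c("constant", "ramp", "ramp_then_decay",
                                        "crossfade"),
                               t_ramp = 3600, t_decay = NULL,
                               decay_width = 1800, floor = 0, t_on = 0) {
  kind <- match.arg(kind)
  if (kind == "ramp_then_decay" && is.null(t_decay)) {
    stop("`t_decay` is required for kind = \"ramp_then_decay\"", call. = FALSE)
  }
  if (floor < 0 || floor > 1) stop("`floor` must be in [0, 1]", call. = FALSE)
  structure(
    list(kind = kind, t_ramp = t_ramp, t_decay = t_decay,
         decay_width = decay_width, floor = floor, t_on = t_on),
    class = "amplitude_envelope")
}

#' Evaluate an amplitude envelope
#'
#' @param envelope an [amplitude_envelope()].
#' @param t time(s) in seconds (vectorized).
#' @return amplitudes in \[0, 1\].
#' @export
envelope_value <- function(envelope, t) {
  stopifnot(inherits(envelope, "amplitude_envelope"))
  e <- envelope
  up <- switch(e$kind,
    constant = rep(1, length(t)),
    ramp = smoothstep((t - e$t_on) / e$t_ramp),
    crossfade = smoothstep((t - e$t_on) / e$t_ramp),
    ramp_then_decay = smoothstep((t - e$t_on) / e$t_ramp))
  if (e$kind == "ramp_then_decay") {
    t0 <- e$t_decay - e$decay_width
    down <- e$floor + (1 - e$floor) * cos_down((t - t0) / e$decay_width)
    up <- up * down
  }
  pmin(pmax(up, 0), 1)
}

#' Assemble a disc-bounded vortex-pair flow model
#'
#' The model superposes the azimuthal velocity profiles of a primary
#' bilateral vortex pair (mirrored across the midline) and, optionally, a
#' secondary pair (an induced axis, rotated ~180 degrees about the disc
#' center). Velocity is tapered smoothly to exactly zero at the disc edge.
#'
#' @param disc_center disc center (um), length 2.
#' @param disc_radius disc radius (um).
#' @param midline_axis_angle angle of the (authentic) midline axis,
#'   radians; `pi/2` puts the midline along +y (anterior up).
#' @param primary_pair list of two [vortex_spec()] with opposite signs.
#' @param secondary_pair optional list of two [vortex_spec()].
#' @param envelopes named list with elements `primary` and (if present)
#'   `secondary`, each an [amplitude_envelope()].
#' @param edge_taper_width width of the cosine taper ring at the disc
#'   margin (um).
#' @param duration total modeled duration (s).
#' @return an object of class `flow_model`.
#' @export
flow_model <- function(disc_center = c(0, 0), disc_radius = 1500,
                       midline_axis_angle = pi / 2,
                       primary_pair, secondary_pair = NULL,
                       envelopes = list(primary = amplitude_envelope("constant")),
                       edge_taper_width = 150, duration = 36000) {
  stopifnot_scalar_pos(disc_radius, "disc_radius")
  check_pair <- function(pair, label) {
    if (length(pair) != 2L ||
        !all(vapply(pair, inherits, logical(1), "vortex_spec"))) {
      stop(sprintf("`%s` must be a list of two vortex_spec", label),
           call. = FALSE)
    }
    if (pair[[1]]$circulation_sign * pair[[2]]$circulation_sign != -1) {
      stop(sprintf("`%s` cores must have opposite circulation signs", label),
           call. = FALSE)
    }
    for (v in pair) {
      if (sqrt(sum((v$center - disc_center)^2)) >= disc_radius) {
        stop(sprintf("`%s` core lies outside the disc", label), call. = FALSE)
      }
    }
  }
  check_pair(primary_pair, "primary_pair")
  if (!is.null(secondary_pair)) {
    check_pair(secondary_pair, "secondary_pair")
    if (is.null(envelopes$secondary)) {
      stop("`envelopes$secondary` required when a secondary pair is present",
           call. = FALSE)
    }
  }
  structure(
    list(disc_center = as.numeric(disc_center),
         disc_radius = disc_radius,
         midline_axis_angle = midline_axis_angle,
         primary_pair = primary_pair,
         secondary_pair = secondary_pair,
         envelopes = envelopes,
         edge_taper_width = edge_taper_width,
         duration = duration),
    class = "flow_model")
}

#' @export
print.flow_model <- function(x, ...) {
  cat("<flow_model>\n")
  cat(sprintf("  disc: center (%g, %g) um, radius %g um\n",
              x$disc_center[1], x$disc_center[2], x$disc_radius))
  cat(sprintf("  midline axis angle: %.3f rad\n", x$midline_axis_angle))
  sep <- sqrt(sum((x$primary_pair[[1]]$center - x$primary_pair[[2]]$center)^2))
  cat(sprintf("  primary pair: separation %s, peak speed %g um/s, envelope %s\n",
              format_um(sep), x$primary_pair[[1]]$peak_speed,
              x$envelopes$primary$kind))
  if (!is.null(x$secondary_pair)) {
    cat(sprintf("  secondary pair: present (envelope %s)\n",
                x$envelopes$secondary$kind))
  }
  cat(sprintf("  duration: %.1f h\n", x$duration / 3600))
  invisible(x)
}

#' Condition presets
#'
#' Named experimental-condition presets for the simulator, emulating the
#' study conditions: `control` (persistent, strengthening bilateral flow),
#' `ddep` (Wnt/PCP suppression: wider vortex separation, otherwise as
#' control), `aphidicolin` (mitotic arrest: flow decays early),
#' `vg1` (ectopic axis induction: a secondary vortex pair, rotated 180
#' degrees about the disc center, switches on after about an hour and
#' overrides the authentic pair), and `vg1_aphidicolin` (induced pair under
#' mitotic arrest: authentic flow fades, induced flow dominates).
#'
#' @return a named list of preset parameter lists.
#' @export
condition_presets <- function() {
  base <- list(
    pair_separation = 860.2,   # um, control left-right rotation distance
    duration_total = 36000,    # s (10 h movie)
    t_ramp = 3600,             # s, strengthening phase
    t_decay = NULL,            # s, no programmed decay
    decay_width = 1800,        # s
    secondary_axis = FALSE,
    secondary_onset = NULL,
    disc_radius = 1500,        # um
    core_radius = 300,         # um
    peak_speed = 0.2,          # um/s
    core_anterior_offset = 0,  # um along the midline
    edge_taper_width = 150,    # um
    left_counterclockwise = TRUE)
  presets <- list(
    control = base,
    ddep = utils::modifyList(base, list(pair_separation = 1008.4)),
    aphidicolin = utils::modifyList(base, list(t_decay = 7920)),  # 2.2 h
    vg1 = utils::modifyList(base, list(secondary_axis = TRUE,
                                       secondary_onset = 3600,
                                       t_decay = 4500)),
    vg1_aphidicolin = utils::modifyList(base, list(secondary_axis = TRUE,
                                                   secondary_onset = 3600,
                                                   t_decay = 4500)))
  presets
}

#' Build a flow model from a condition preset
#'
#' Deterministically translates a named preset (plus optional field
#' overrides) into a [flow_model()]. The primary pair is mirrored across
#' the midline at the preset separation; for `vg1`-type presets a secondary
#' pair, rotated 180 degrees about the disc center, crossfades in at
#' `secondary_onset` while the authentic pair fades out.
#'
#' @param preset preset name; see [condition_presets()].
#' @param overrides named list overriding preset fields (e.g.
#'   `pair_separation`, `peak_speed`, `duration_total`).
#' @return a [flow_model()].
#' @export
#' @examples
#' m <- build_flow_model("control")
#' m
build_flow_model <- function(preset = "control", overrides = list()) {
  presets <- condition_presets()
  if (!is.character(preset) || length(preset) != 1L ||
      !preset %in% names(presets)) {
    stop(sprintf("unknown preset %s; valid presets: %s",
                 deparse(substitute(preset)),
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  p <- presets[[preset]]
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown)) {
    stop(sprintf("unknown override field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  p <- utils::modifyList(p, overrides)
  if (p$pair_separation >= 2 * p$disc_radius) {
    stop("`pair_separation` must be smaller than the disc diameter",
         call. = FALSE)
  }

  # Midline along angle theta; cores sit at +/- separation/2 along the
  # perpendicular, at core_anterior_offset along the midline.
  theta <- pi / 2
  mid_dir <- c(cos(theta), sin(theta))
  perp <- c(-mid_dir[2], mid_dir[1])        # embryo's left (+y-up coords)
  half <- p$pair_separation / 2
  left_sign <- if (p$left_counterclockwise) +1 else -1
  mk_pair <- function(center, flip) {
    off <- p$core_anterior_offset * mid_dir * flip
    l <- vortex_spec(center + off + perp * half * flip,
                     left_sign * flip, p$peak_speed, p$core_radius)
    r <- vortex_spec(center + off - perp * half * flip,
                     -left_sign * flip, p$peak_speed, p$core_radius)
    list(l, r)
  }
  disc_center <- c(0, 0)
  primary <- mk_pair(disc_center, +1)

  if (isTRUE(p$secondary_axis)) {
    envs <- list(
      primary = amplitude_envelope("ramp_then_decay", t_ramp = p$t_ramp,
                                   t_decay = p$t_decay,
                                   decay_width = p$decay_width),
      secondary = amplitude_envelope("crossfade", t_ramp = p$t_ramp / 2,
                                     t_on = p$secondary_onset))
    secondary <- mk_pair(disc_center, -1)  # rotated pi about disc center
  } else if (!is.null(p$t_decay)) {
    envs <- list(primary = amplitude_envelope("ramp_then_decay",
                                              t_ramp = p$t_ramp,
                                              t_decay = p$t_decay,
                                              decay_width = p$decay_width))
    secondary <- NULL
  } else {
    envs <- list(primary = amplitude_envelope("ramp", t_ramp = p$t_ramp))
    secondary <- NULL
  }

  flow_model(disc_center = disc_center, disc_radius = p$disc_radius,
             midline_axis_angle = theta,
             primary_pair = primary, secondary_pair = secondary,
             envelopes = envs, edge_taper_width = p$edge_taper_width,
             duration = p$duration_total)
}

# Velocity contribution of one vortex at points (n x 2 matrix), no envelope.
vortex_velocity <- function(spec, pts) {
  dx <- pts[, 1] - spec$center[1]
  dy <- pts[, 2] - spec$center[2]
  r <- sqrt(dx * dx + dy * dy)
  s <- r / spec$core_radius
  # u_theta(r) / r: tangential speed over radius, finite (-> 0) at r = 0
  amp <- numeric(length(r))
  nz <- r > 0
  amp[nz] <- spec$circulation_sign * spec$peak_speed / LAMB_OSEEN_PEAK *
    (1 - exp(-LAMB_OSEEN_ALPHA * s[nz]^2)) / (s[nz] * r[nz])
  cbind(-amp * dy, amp * dx)
}

#' Evaluate the model velocity field
#'
#' Superposes the per-vortex azimuthal profiles, modulated by each pair's
#' amplitude envelope, and applies the radial cosine edge taper. Velocity
#' is exactly zero at and outside the disc edge.
#'
#' @param model a [flow_model()].
#' @param points n x 2 matrix (or length-2 vector) of positions (um).
#' @param t time (s), scalar.
#' @return n x 2 matrix of velocities (um/s).
#' @export
velocity_at <- function(model, points, t) {
  stopifnot(inherits(model, "flow_model"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("non-finite point(s)", call. = FALSE)
  if (!is.finite(t) || length(t) != 1L) stop("`t` must be a finite scalar",
                                             call. = FALSE)
  v <- matrix(0, nrow(points), 2)
  e1 <- envelope_value(model$envelopes$primary, t)
  if (e1 > 0) {
    for (spec in model$primary_pair) v <- v + e1 * vortex_velocity(spec, points)
  }
  if (!is.null(model$secondary_pair)) {
    e2 <- envelope_value(model$envelopes$secondary, t)
    if (e2 > 0) {
      for (spec in model$secondary_pair) {
        v <- v + e2 * vortex_velocity(spec, points)
      }
    }
  }
  # radial edge taper to zero at the disc margin
  rr <- sqrt((points[, 1] - model$disc_center[1])^2 +
             (points[, 2] - model$disc_center[2])^2)
  w <- model$edge_taper_width
  taper <- cos_down((rr - (model$disc_radius - w)) / w)
  taper[rr >= model$disc_radius] <- 0
  v * taper
}
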