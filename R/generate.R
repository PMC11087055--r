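# Fixture factory: preset -> (movie, ground truth, model).

#' Generate a complete synthetic condition
#'
#' Seeds tracer particles uniformly in the disc, advects them through the
#' preset's flow model, and renders the time-lapse movie. Returns the
#' movie together with the full ground truth. All randomness (seeding and
#' rendering noise) flows through `seed`.
#'
#' @param preset condition preset name; see [condition_presets()].
#' @param imaging an [imaging_params()]; its `frame_count` and
#'   `frame_interval` define the movie span (which also caps the model
#'   duration).
#' @param n_particles number of tracer particles (> 0).
#' @param seed integer seed.
#' @param overrides preset overrides forwarded to [build_flow_model()].
#' @param out_dir optional directory; when given, writes `movie.tif`,
#'   `trajectories.csv` and a `manifest.json` describing all parameters.
#' @return list with elements `stack` (image_stack), `ensemble`
#'   (particle_ensemble), and `model` (flow_model).
#' @export
#' @examples
#' sim <- generate_condition("control",
#'   imaging = imaging_params(frame_count = 4, image_shape = c(256L, 256L)),
#'   n_particles = 100, seed = 1)
#' sim$stack
generate_condition <- function(preset, imaging = imaging_params(),
                               n_particles = 8000, seed = 1L,
                               overrides = list(), out_dir = NULL) {
  stopifnot_scalar_pos(n_particles, "n_particles")
  movie_span <- imaging$frame_interval * (imaging$frame_count - 1)
  overrides <- utils::modifyList(list(duration_total = movie_span), overrides)
  model <- build_flow_model(preset, overrides)
  times <- imaging$frame_interval * (seq_len(imaging$frame_count) - 1)

  init <- with_seed(seed, {
    r <- model$disc_radius * sqrt(stats::runif(n_particles))
    a <- stats::runif(n_particles, 0, 2 * pi)
    cbind(model$disc_center[1] + r * cos(a),
          model$disc_center[2] + r * sin(a))
  })
  ensemble <- advect_particles(model, init, times)
  stack <- render_frames(ensemble, imaging, seed = seed + 1L)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_image_stack(stack, file.path(out_dir, "movie.tif"))
    write_trajectories(ensemble, file.path(out_dir, "trajectories.csv"))
    manifest <- list(
      preset = preset, seed = seed, n_particles = n_particles,
      overrides = overrides,
      imaging = unclass(imaging),
      disc_radius = model$disc_radius,
      pair_separation = sqrt(sum((model$primary_pair[[1]]$center -
                                  model$primary_pair[[2]]$center)^2)),
      duration_s = model$duration)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(stack = stack, ensemble = ensemble, model = model)
}
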