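# End-to-end orchestration: simulate -> PIV -> fields -> metrics -> stats.

#' Default pipeline configuration
#'
#' Central defaults for every stage: conditions and seeds, imaging
#' parameters (180 s frame interval), PIV windows (64/32 px, 50% overlap),
#' analysis windows (30 min sliding window; 6 h separation average), and
#' the 3x3 / 800 um quantification grid.
#'
#' @return a named list (a valid config).
#' @export
default_config <- function() {
  list(
    conditions = c("control", "ddep"),
    seeds = 1:4,
    n_particles = 8000,
    overrides = list(),          # per-condition preset overrides
    imaging = list(pixel_size = 3.25, frame_interval = 180,
                   frame_count = 200, image_shape = c(1024L, 1024L),
                   spot_sigma = 2, spot_amplitude = 8000,
                   background_level = 400, noise_model = "gaussian",
                   noise_sd = 60, bit_depth = 16),
    piv = list(pass1_window = 64L, pass2_window = 32L,
               overlap_fraction = 0.5, highpass_kernel = 15L,
               outlier_threshold = 2.0, median_eps = 0.1,
               smoothing = TRUE),
    piv_stride = 3L,             # analyze every piv_stride-th frame pair
    analysis = list(window_s = 1800, separation_hours = 6,
                    midline_angle = pi / 2, min_separation = 200,
                    bridge = 1L),
    quant = list(n_per_side = 3L, side_um = 800))
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults from [default_config()], flags unknown keys, and checks
#' value ranges; all problems are reported together.
#'
#' @param config a (possibly partial) named list.
#' @return the normalized config, or an error listing every problem.
#' @export
validate_config <- function(config = list()) {
  if (!is.list(config)) stop("`config` must be a list", call. = FALSE)
  def <- default_config()
  errs <- character(0)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    errs <- c(errs, sprintf("unknown key(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  for (sub in c("imaging", "piv", "analysis", "quant")) {
    if (!is.null(config[[sub]])) {
      bad <- setdiff(names(config[[sub]]), names(def[[sub]]))
      if (length(bad)) {
        errs <- c(errs, sprintf("unknown key(s) in `%s`: %s", sub,
                                paste(bad, collapse = ", ")))
      }
    }
  }
  cfg <- utils::modifyList(def, config[intersect(names(config), names(def))])

  presets <- names(condition_presets())
  bad_cond <- setdiff(cfg$conditions, presets)
  if (length(bad_cond)) {
    errs <- c(errs, sprintf("unknown preset(s) %s; valid presets: %s",
                            paste(bad_cond, collapse = ", "),
                            paste(presets, collapse = ", ")))
  }
  if (anyDuplicated(cfg$seeds)) errs <- c(errs, "`seeds` must be distinct")
  ov <- cfg$piv$overlap_fraction
  if (ov < 0 || ov >= 1) {
    errs <- c(errs,
              sprintf("`piv$overlap_fraction` = %g outside valid range [0, 1)",
                      ov))
  }
  for (key in c("pixel_size", "frame_interval", "frame_count")) {
    if (cfg$imaging[[key]] <= 0) {
      errs <- c(errs, sprintf("`imaging$%s` must be positive", key))
    }
  }
  if (cfg$analysis$window_s <= 0) {
    errs <- c(errs, "`analysis$window_s` must be positive")
  }
  if (length(errs)) {
    stop(paste(c("invalid configuration:", paste(" -", errs)),
               collapse = "\n"), call. = FALSE)
  }
  cfg
}

#' PIV-analyze an image stack into a physical field series
#'
#' High-pass filters all frames once, runs [two_pass_piv()] on consecutive
#' frame pairs (every `stride`-th pair), and converts the results to
#' calibrated physical (y-up) fields on a common grid.
#'
#' @param stack an `image_stack`.
#' @param params a [piv_params()].
#' @param stride analyze pairs `(i, i+1)` for `i = 1, 1+stride, ...`.
#' @return a [field_series()] in `um_per_s`.
#' @export
piv_series <- function(stack, params = piv_params(), stride = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  nt <- length(stack$frames)
  if (nt < 2L) stop("stack must have at least two frames", call. = FALSE)
  frames <- stack$frames
  if (!is.null(params$highpass_kernel)) {
    frames <- lapply(frames, highpass_filter, kernel = params$highpass_kernel)
  }
  shape <- dim(frames[[1]])
  idx <- seq.int(1L, nt - 1L, by = as.integer(stride))
  fields <- lapply(idx, function(i) {
    f <- two_pass_piv(frames[[i]], frames[[i + 1L]], params,
                      preprocess = FALSE)
    f$t <- stack$times[i]
    as_physical_field(f, shape, stack$pixel_size, stack$frame_interval)
  })
  field_series(fields)
}

run_one <- function(condition, seed, cfg, out_dir = NULL, quiet = TRUE) {
  imaging <- do.call(imaging_params, cfg$imaging)
  sim <- generate_condition(condition, imaging,
                            n_particles = cfg$n_particles, seed = seed,
                            overrides = cfg$overrides[[condition]] %||% list(),
                            out_dir = out_dir)
  params <- do.call(piv_params, cfg$piv)
  series <- piv_series(sim$stack, params, stride = cfg$piv_stride)

  span <- max(series$times)
  avg <- time_average(series, 0, min(cfg$analysis$separation_hours * 3600,
                                     span))
  # cores are sought only inside the disc proper: the taper ring at the
  # margin mixes tissue with empty background and carries no reliable PIV
  # signal
  pp <- polonaise_params(min_separation = cfg$analysis$min_separation,
                         max_core_radius = sim$model$disc_radius -
                           sim$model$edge_taper_width,
                         bridge = cfg$analysis$bridge)
  pattern <- detect_polonaise(avg, cfg$analysis$midline_angle, pp)
  dur <- polonaise_duration(series, cfg$analysis$midline_angle,
                            window = cfg$analysis$window_s, pp)
  true_sep <- sqrt(sum((sim$model$primary_pair[[1]]$center -
                        sim$model$primary_pair[[2]]$center)^2))
  if (!quiet) {
    message(sprintf("  %s seed %d: separation %s (truth %s), duration %.2f h",
                    condition, seed,
                    if (pattern$detected) format_um(pattern$separation) else "NA",
                    format_um(true_sep), dur$duration_h))
  }
  if (!is.null(out_dir)) {
    for (i in seq_along(series$fields)) {
      write_velocity_field(series$fields[[i]],
                           file.path(out_dir, sprintf("field_%04d.csv", i)),
                           meta = list(condition = condition, seed = seed))
    }
  }
  list(condition = condition, seed = seed,
       detected = pattern$detected,
       separation_um = if (pattern$detected) pattern$separation else NA_real_,
       true_separation_um = true_sep,
       duration_h = dur$duration_h,
       detected_fraction = mean(dur$detected),
       pattern = pattern, duration = dur)
}

#' Run the full analysis pipeline
#'
#' For each condition and seed: generates the synthetic movie, recovers
#' the velocity fields by two-pass PIV, measures the vortex-pair
#' separation on the time-averaged field and the pattern duration on
#' sliding windows, then compares conditions (pooled two-tailed Student's
#' t on separations and durations for each condition pair). The report is
#' fully determined by the config content (including its seeds).
#'
#' @param config a config list; see [default_config()] and
#'   [validate_config()].
#' @param out_dir optional output root; per-run artifacts and the JSON
#'   report are written beneath it.
#' @param quiet suppress progress messages.
#' @return an object of class `run_report`: `metrics` (data frame with
#'   one row per condition x seed), `comparisons`, `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, quiet = TRUE) {
  cfg <- validate_config(config)
  runs <- list()
  for (cond in cfg$conditions) {
    for (sd in cfg$seeds) {
      sub <- if (!is.null(out_dir)) {
        file.path(out_dir, sprintf("%s_seed%d", cond, sd))
      } else NULL
      res <- tryCatch(
        run_one(cond, sd, cfg, out_dir = sub, quiet = quiet),
        error = function(e) {
          list(condition = cond, seed = sd, detected = FALSE,
               separation_um = NA_real_, true_separation_um = NA_real_,
               duration_h = NA_real_, detected_fraction = NA_real_,
               failed = conditionMessage(e))
        })
      runs[[length(runs) + 1L]] <- res
    }
  }
  metrics <- data.frame(
    condition = vapply(runs, `[[`, character(1), "condition"),
    seed = vapply(runs, `[[`, numeric(1), "seed"),
    detected = vapply(runs, `[[`, logical(1), "detected"),
    separation_um = vapply(runs, `[[`, numeric(1), "separation_um"),
    true_separation_um = vapply(runs, `[[`, numeric(1),
                                "true_separation_um"),
    duration_h = vapply(runs, `[[`, numeric(1), "duration_h"),
    detected_fraction = vapply(runs, `[[`, numeric(1), "detected_fraction"),
    failed = vapply(runs, function(r) r$failed %||% "", character(1)))

  comparisons <- list()
  conds <- unique(metrics$condition)
  if (length(conds) >= 2L) {
    for (i in seq_len(length(conds) - 1L)) {
      for (j in (i + 1L):length(conds)) {
        a <- conds[i]; b <- conds[j]
        key <- paste(a, "vs", b)
        sep_a <- metrics$separation_um[metrics$condition == a]
        sep_b <- metrics$separation_um[metrics$condition == b]
        dur_a <- metrics$duration_h[metrics$condition == a]
        dur_b <- metrics$duration_h[metrics$condition == b]
        cmp <- list()
        if (sum(is.finite(sep_a)) >= 2 && sum(is.finite(sep_b)) >= 2) {
          cmp$separation <- compare_groups(stats::setNames(list(sep_a, sep_b),
                                                           c(a, b)))
        }
        if (sum(is.finite(dur_a)) >= 2 && sum(is.finite(dur_b)) >= 2) {
          cmp$duration <- compare_groups(stats::setNames(list(dur_a, dur_b),
                                                         c(a, b)))
        }
        comparisons[[key]] <- cmp
      }
    }
  }
  report <- structure(list(metrics = metrics, comparisons = comparisons,
                           config = cfg),
                      class = "run_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report
}

report_to_list <- function(report) {
  cmps <- lapply(report$comparisons, function(cmp) {
    lapply(cmp, function(gc) {
      list(test = gc$test, statistic = gc$statistic, df = gc$df, p = gc$p,
           groups = gc$summaries)
    })
  })
  list(metrics = report$metrics, comparisons = cmps,
       config_hash = digest_config(report$config))
}

# Cheap content hash of the config (no external deps): serialize to a
# canonical JSON string and fold into an integer checksum.
digest_config <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 997)) %% 2147483647
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  m <- x$metrics
  for (cond in unique(m$condition)) {
    sub <- m[m$condition == cond, ]
    cat(sprintf(paste0("  %s: %d runs, separation %.1f +/- %.1f um, ",
                       "duration %.2f +/- %.2f h\n"),
                cond, nrow(sub),
                mean(sub$separation_um, na.rm = TRUE),
                stats::sd(sub$separation_um, na.rm = TRUE),
                mean(sub$duration_h, na.rm = TRUE),
                stats::sd(sub$duration_h, na.rm = TRUE)))
  }
  for (key in names(x$comparisons)) {
    for (what in names(x$comparisons[[key]])) {
      gc <- x$comparisons[[key]][[what]]
      cat(sprintf("  %s (%s): t = %.3f, p = %.4g\n", key, what,
                  gc$statistic, gc$p))
    }
  }
  invisible(x)
}

#' @export
summary.run_report <- function(object, ...) {
  print(object)
  invisible(object)
}
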