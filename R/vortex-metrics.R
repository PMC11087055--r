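# Detection of counter-rotating vortex pairs, their separation, and the
# persistence of the bilateral flow pattern.

#' Detection parameters for the bilateral vortex pattern
#'
#' @param min_abs_vorticity absolute vorticity threshold (1/s) for a core;
#'   `NULL` uses 20% of the 95th percentile of |vorticity| over the data
#'   being analyzed (movie-wide when analyzing a series), a scale-free
#'   default.
#' @param min_separation non-maximum-suppression radius between cores
#'   (um).
#' @param origin point on the midline (um), typically the disc center.
#' @param max_core_radius maximum distance of a core from `origin` (um);
#'   cores beyond it (outside the embryonic disc, where the field carries
#'   no tissue signal) are ignored. `Inf` disables the restriction.
#' @param bridge number of consecutive undetected windows tolerated
#'   inside a detected run when scoring duration (0 = strict).
#' @return an object of class `polonaise_params`.
#' @export
polonaise_params <- function(min_abs_vorticity = NULL, min_separation = 200,
                             origin = c(0, 0), max_core_radius = Inf,
                             bridge = 1L) {
  structure(list(min_abs_vorticity = min_abs_vorticity,
                 min_separation = min_separation,
                 origin = as.numeric(origin),
                 max_core_radius = max_core_radius,
                 bridge = as.integer(bridge)),
            class = "polonaise_params")
}

# Logical matrix: grid nodes within `radius` of `origin`.
grid_within_radius <- function(x, y, origin, radius) {
  if (!is.finite(radius)) return(matrix(TRUE, length(y), length(x)))
  dx <- outer(rep(1, length(y)), x) - origin[1]
  dy <- outer(y, rep(1, length(x))) - origin[2]
  sqrt(dx^2 + dy^2) <= radius
}

default_vorticity_threshold <- function(abs_w, frac = 0.2, prob = 0.95) {
  frac * stats::quantile(abs_w, prob, na.rm = TRUE, names = FALSE)
}

#' Detect vortex cores in a vorticity map
#'
#' Finds local extrema of the vorticity with `|vorticity| >=
#' min_abs_vorticity`, suppresses non-maximal extrema within
#' `min_separation`, and refines each core position by a
#' vorticity-weighted centroid over the extremum's 3x3 neighborhood.
#' Cores are returned sorted by decreasing `|peak_vorticity|`.
#'
#' @param vorticity_map a `scalar_field` of kind `"vorticity"`.
#' @param min_abs_vorticity threshold (1/s); `NULL` uses the scale-free
#'   default of [polonaise_params()] on this map.
#' @param min_separation suppression radius (um).
#' @return a list of `vortex_core` objects (possibly empty), each with
#'   `position` (um), `sign`, `peak_vorticity` (1/s), `support_radius`
#'   (um).
#' @export
detect_cores <- function(vorticity_map, min_abs_vorticity = NULL,
                         min_separation = 200) {
  stopifnot(inherits(vorticity_map, "scalar_field"))
  w <- vorticity_map$values
  ok <- vorticity_map$valid & is.finite(w)
  if (!any(ok)) stop("vorticity map has no valid nodes", call. = FALSE)
  if (is.null(min_abs_vorticity)) {
    min_abs_vorticity <- default_vorticity_threshold(abs(w[ok]))
  }
  nb <- neighbor_stack(ifelse(ok, w, NA_real_))
  nb_max <- suppressWarnings(apply(nb, 1L, max, na.rm = TRUE))
  nb_min <- suppressWarnings(apply(nb, 1L, min, na.rm = TRUE))
  wv <- as.vector(w)
  cand <- as.vector(ok) & abs(wv) >= min_abs_vorticity &
    ((wv > 0 & wv >= nb_max) | (wv < 0 & wv <= nb_min))
  idx <- which(cand)
  if (!length(idx)) return(list())
  ny <- length(vorticity_map$y)
  iy <- (idx - 1L) %% ny + 1L
  ix <- (idx - 1L) %/% ny + 1L
  px <- vorticity_map$x[ix]; py <- vorticity_map$y[iy]
  ord <- order(-abs(wv[idx]))
  keep <- logical(length(idx))
  for (k in ord) {
    if (any(keep & sqrt((px - px[k])^2 + (py - py[k])^2) < min_separation)) {
      next
    }
    keep[k] <- TRUE
  }
  sel <- which(keep)[order(-abs(wv[idx[keep]]))]

  sp <- grid_spacing(vorticity_map)
  cores <- lapply(sel, function(k) {
    cy <- iy[k]; cx <- ix[k]
    s <- sign(wv[idx[k]])
    ry <- max(1L, cy - 1L):min(ny, cy + 1L)
    rx <- max(1L, cx - 1L):min(length(vorticity_map$x), cx + 1L)
    wt <- pmax(s * w[ry, rx, drop = FALSE], 0)
    wt[!ok[ry, rx, drop = FALSE]] <- 0
    tot <- sum(wt)
    pos <- if (tot > 0) {
      c(sum(outer(rep(1, length(ry)), vorticity_map$x[rx]) * wt) / tot,
        sum(outer(vorticity_map$y[ry], rep(1, length(rx))) * wt) / tot)
    } else c(vorticity_map$x[cx], vorticity_map$y[cy])
    # equivalent radius of the same-sign half-max region near the core
    dx_all <- outer(rep(1, ny), vorticity_map$x) - pos[1]
    dy_all <- outer(vorticity_map$y, rep(1, length(vorticity_map$x))) - pos[2]
    near <- sqrt(dx_all^2 + dy_all^2) <= 2 * min_separation
    n_half <- sum(ok & near & s * w >= abs(wv[idx[k]]) / 2)
    structure(list(position = pos, sign = s,
                   peak_vorticity = wv[idx[k]],
                   support_radius = sqrt(n_half * abs(prod(sp)) / pi)),
              class = "vortex_core")
  })
  cores
}

#' Detect the bilateral counter-rotating vortex pair
#'
#' Computes the vorticity of an averaged, calibrated velocity field,
#' detects vortex cores, and selects the strongest pair with opposite
#' rotation signs lying on opposite sides of the midline. Non-detection is
#' a result (with reasons), not an error. Calling with the midline rotated
#' by pi scores the pattern along an induced (secondary) axis.
#'
#' Core positions are taken from vorticity extrema, a deterministic,
#' grid-local criterion; this replaces the manual identification of
#' rotation centers from streamline plots used in microscopy practice.
#'
#' @param avg_field a calibrated `velocity_field` (um_per_s).
#' @param midline_angle midline axis angle (radians; `pi/2` = anterior
#'   up).
#' @param params a [polonaise_params()].
#' @param axis_label `"authentic"` or `"induced"` tag carried in the
#'   result.
#' @return an object of class `polonaise_pattern`: `left_core`,
#'   `right_core`, `midline_angle`, `separation` (um or NA), `detected`,
#'   `reasons`, `axis_label`.
#' @export
detect_polonaise <- function(avg_field, midline_angle = pi / 2,
                             params = polonaise_params(),
                             axis_label = "authentic") {
  stopifnot(inherits(avg_field, "velocity_field"))
  vmap <- vorticity(avg_field)
  in_disc <- grid_within_radius(vmap$x, vmap$y, params$origin,
                                params$max_core_radius)
  vmap$valid <- vmap$valid & in_disc
  thr <- params$min_abs_vorticity
  if (is.null(thr)) {
    thr <- default_vorticity_threshold(abs(vmap$values[vmap$valid]))
  }
  cores <- tryCatch(
    detect_cores(vmap, min_abs_vorticity = thr,
                 min_separation = params$min_separation),
    error = function(e) list())
  mk <- function(left, right, detected, reasons) {
    sep <- if (detected) {
      sqrt(sum((left$position - right$position)^2))
    } else NA_real_
    structure(list(left_core = left, right_core = right,
                   midline_angle = midline_angle, separation = sep,
                   detected = detected, reasons = reasons,
                   axis_label = axis_label,
                   threshold = thr),
              class = "polonaise_pattern")
  }
  if (length(cores) < 1L) {
    return(mk(NULL, NULL, FALSE, "no cores"))
  }
  d <- c(cos(midline_angle), sin(midline_angle))
  side <- vapply(cores, function(cr) {
    p <- cr$position - params$origin
    sign(d[1] * p[2] - d[2] * p[1])
  }, numeric(1))
  signs <- vapply(cores, function(cr) cr$sign, numeric(1))
  mags <- vapply(cores, function(cr) abs(cr$peak_vorticity), numeric(1))

  best <- NULL; best_score <- -Inf
  n <- length(cores)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (signs[i] * signs[j] >= 0) next
        if (side[i] * side[j] >= 0) next
        score <- mags[i] + mags[j]
        if (score > best_score) { best_score <- score; best <- c(i, j) }
      }
    }
  }
  if (is.null(best)) {
    return(mk(NULL, NULL, FALSE, "no opposite-signed bilateral pair"))
  }
  li <- if (side[best[1]] > 0) best[1] else best[2]
  ri <- setdiff(best, li)
  mk(cores[[li]], cores[[ri]], TRUE, character(0))
}

#' @export
print.polonaise_pattern <- function(x, ...) {
  if (x$detected) {
    cat(sprintf(paste0("<polonaise_pattern> detected (%s axis)\n",
                       "  separation: %s\n",
                       "  left core:  (%.1f, %.1f) um, sign %+d, peak %.2e 1/s\n",
                       "  right core: (%.1f, %.1f) um, sign %+d, peak %.2e 1/s\n"),
                x$axis_label, format_um(x$separation),
                x$left_core$position[1], x$left_core$position[2],
                x$left_core$sign, x$left_core$peak_vorticity,
                x$right_core$position[1], x$right_core$position[2],
                x$right_core$sign, x$right_core$peak_vorticity))
  } else {
    cat(sprintf("<polonaise_pattern> not detected (%s axis): %s\n",
                x$axis_label, paste(x$reasons, collapse = "; ")))
  }
  invisible(x)
}

#' Left-right separation of a detected vortex pair
#'
#' Euclidean distance between the two core positions (um).
#'
#' @param pattern a detected `polonaise_pattern`.
#' @return separation in um.
#' @export
measure_separation <- function(pattern) {
  stopifnot(inherits(pattern, "polonaise_pattern"))
  if (!isTRUE(pattern$detected)) {
    stop("pattern was not detected; check `detected` before measuring",
         call. = FALSE)
  }
  sqrt(sum((pattern$left_core$position - pattern$right_core$position)^2))
}

#' Persistence of the bilateral flow pattern
#'
#' Slides a time-averaging window across the field series, runs
#' [detect_polonaise()] on each window average, and scores the duration
#' of the maximal contiguous detected run starting at the first detected
#' window (t0, the initiation of the flow). Up to `params$bridge`
#' consecutive undetected windows are tolerated inside a run. The
#' vorticity threshold, when not given, is movie-wide: 20% of the 95th
#' percentile of |vorticity| pooled over all windows.
#'
#' @param series a [field_series()] of calibrated fields.
#' @param midline_angle midline axis angle (radians).
#' @param window averaging window length (s); default 1800 s (30 min).
#' @param params a [polonaise_params()].
#' @return an object of class `duration_result`: `t0`, `t_end` (s),
#'   `duration_h`, `detected` flags, window start times, and per-window
#'   peak |vorticity|.
#' @export
polonaise_duration <- function(series, midline_angle = pi / 2,
                               window = 1800, params = polonaise_params()) {
  stopifnot(inherits(series, "field_series"))
  tmax <- max(series$times)
  starts <- series$times[series$times + window <= tmax + 1e-9]
  if (length(starts) < 2L) stop("series must span at least two windows",
                                call. = FALSE)
  avgs <- lapply(starts, function(t0) time_average(series, t0, t0 + window))
  if (is.null(params$min_abs_vorticity)) {
    f1 <- avgs[[1]]
    in_disc <- grid_within_radius(f1$x, f1$y, params$origin,
                                  params$max_core_radius)
    allw <- unlist(lapply(avgs, function(f) {
      vm <- vorticity(f)
      abs(vm$values[vm$valid & in_disc])
    }))
    params$min_abs_vorticity <- default_vorticity_threshold(allw)
  }
  pats <- lapply(avgs, detect_polonaise, midline_angle = midline_angle,
                 params = params)
  det <- vapply(pats, function(p) isTRUE(p$detected), logical(1))
  peak_w <- vapply(seq_along(pats), function(i) {
    p <- pats[[i]]
    if (p$detected) {
      max(abs(p$left_core$peak_vorticity), abs(p$right_core$peak_vorticity))
    } else NA_real_
  }, numeric(1))

  if (!any(det)) {
    return(structure(list(t0 = NA_real_, t_end = NA_real_, duration_h = 0,
                          detected = det, window_starts = starts,
                          peak_vorticity = peak_w, window = window,
                          threshold = params$min_abs_vorticity,
                          never_detected = TRUE),
                     class = "duration_result"))
  }
  first <- which(det)[1]
  last <- first
  gap <- 0L
  i <- first
  while (i < length(det)) {
    i <- i + 1L
    if (det[i]) { last <- i; gap <- 0L } else {
      gap <- gap + 1L
      if (gap > params$bridge) break
    }
  }
  t0 <- starts[first]
  t_end <- starts[last] + window
  structure(list(t0 = t0, t_end = t_end,
                 duration_h = (t_end - t0) / 3600,
                 detected = det, window_starts = starts,
                 peak_vorticity = peak_w, window = window,
                 threshold = params$min_abs_vorticity,
                 never_detected = FALSE),
            class = "duration_result")
}

#' @export
print.duration_result <- function(x, ...) {
  if (isTRUE(x$never_detected)) {
    cat("<duration_result> pattern never detected (duration 0 h)\n")
  } else {
    cat(sprintf(paste0("<duration_result> duration %.2f h ",
                       "(t0 = %.2f h, t_end = %.2f h; %d/%d windows detected)\n"),
                x$duration_h, x$t0 / 3600, x$t_end / 3600,
                sum(x$detected), length(x$detected)))
  }
  invisible(x)
}
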