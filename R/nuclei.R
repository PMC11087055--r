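# Grid-based quantification of labeled-nucleus fractions (BrdU/TUNEL-style
# assays on synthetic two-channel data).

#' Generate a synthetic nucleus field
#'
#' Places nuclei by a homogeneous Poisson process on the embryonic disc
#' and labels each independently with probability `p_labeled` (emulating,
#' e.g., BrdU incorporation or TUNEL positivity). Optionally renders the
#' field as a two-channel image pair (all nuclei / labeled nuclei).
#'
#' @param density nuclei per um^2 (> 0).
#' @param p_labeled labeling probability in \[0, 1\].
#' @param disc_center disc center (um).
#' @param disc_radius disc radius (um).
#' @param seed integer seed.
#' @param render optional [imaging_params()]; when given, the result also
#'   carries `images`, a list of two matrices (channel "all" = every
#'   nucleus, channel "labeled" = labeled nuclei only).
#' @return an object of class `nucleus_field`: `positions` (n x 2, um),
#'   `labeled` (logical), disc geometry, `seed`, optional `images`.
#' @export
generate_nuclei <- function(density, p_labeled, disc_center = c(0, 0),
                            disc_radius = 1500, seed = 1L, render = NULL) {
  stopifnot_scalar_pos(density, "density")
  if (p_labeled < 0 || p_labeled > 1) {
    stop("`p_labeled` must be in [0, 1]", call. = FALSE)
  }
  out <- with_seed(seed, {
    n <- stats::rpois(1L, density * pi * disc_radius^2)
    r <- disc_radius * sqrt(stats::runif(n))
    a <- stats::runif(n, 0, 2 * pi)
    pos <- cbind(disc_center[1] + r * cos(a), disc_center[2] + r * sin(a))
    lab <- stats::runif(n) < p_labeled
    list(pos = pos, lab = lab)
  })
  nf <- structure(list(positions = out$pos, labeled = out$lab,
                       disc_center = as.numeric(disc_center),
                       disc_radius = disc_radius, seed = seed),
                  class = "nucleus_field")
  if (!is.null(render)) {
    shape <- render$image_shape
    all_px <- um_to_px(out$pos, shape, render$pixel_size)
    lab_px <- um_to_px(out$pos[out$lab, , drop = FALSE], shape,
                       render$pixel_size)
    nf$images <- list(
      all = render_spots(all_px, shape, sigma = render$spot_sigma,
                         amplitude = render$spot_amplitude,
                         background = render$background_level),
      labeled = render_spots(lab_px, shape, sigma = render$spot_sigma,
                             amplitude = render$spot_amplitude,
                             background = render$background_level))
    nf$pixel_size <- render$pixel_size
  }
  nf
}

#' @export
print.nucleus_field <- function(x, ...) {
  cat(sprintf("<nucleus_field> %d nuclei (%.1f%% labeled) on a %s-radius disc\n",
              nrow(x$positions), 100 * mean(x$labeled),
              format_um(x$disc_radius)))
  invisible(x)
}

#' Place the counting grid on the disc
#'
#' A contiguous `n_per_side` x `n_per_side` block of axis-aligned squares
#' (side 800 um by default, giving the standard 3x3 / 2400 x 2400 um
#' layout) centered on the disc center, returned in row-major order (top
#' row first, y decreasing).
#'
#' @param disc_center grid center (um).
#' @param n_per_side squares per side (>= 1).
#' @param side square side length (um).
#' @param disc_radius optional; warn when the grid extends beyond the
#'   disc.
#' @return an object of class `quant_grid`: data frame `squares` with
#'   columns `row`, `col`, `xmin`, `xmax`, `ymin`, `ymax`, plus `side`.
#' @export
place_grid <- function(disc_center = c(0, 0), n_per_side = 3L, side = 800,
                       disc_radius = NULL) {
  if (n_per_side < 1L) stop("`n_per_side` must be >= 1", call. = FALSE)
  stopifnot_scalar_pos(side, "side")
  half <- n_per_side * side / 2
  if (!is.null(disc_radius) && half * sqrt(2) > disc_radius) {
    warning("grid corners extend beyond the disc radius", call. = FALSE)
  }
  # row-major, top row (largest y) first
  rows <- rep(seq_len(n_per_side), each = n_per_side)
  cols <- rep(seq_len(n_per_side), times = n_per_side)
  xmin <- disc_center[1] - half + (cols - 1) * side
  ymax <- disc_center[2] + half - (rows - 1) * side
  squares <- data.frame(row = rows, col = cols,
                        xmin = xmin, xmax = xmin + side,
                        ymin = ymax - side, ymax = ymax)
  structure(list(squares = squares, side = side, n_per_side = n_per_side,
                 center = as.numeric(disc_center)),
            class = "quant_grid")
}

#' @export
print.quant_grid <- function(x, ...) {
  cat(sprintf("<quant_grid> %d x %d squares of %s side (%.2f mm^2 total)\n",
              x$n_per_side, x$n_per_side, format_um(x$side),
              nrow(x$squares) * (x$side / 1000)^2))
  if (!is.null(x$squares$fraction)) {
    fr <- x$squares$fraction
    cat(sprintf("  mean per-square labeled fraction: %.4f (%d/%d squares)\n",
                mean(fr, na.rm = TRUE), sum(!is.na(fr)), length(fr)))
  }
  invisible(x)
}

#' Detect fluorescent spots in an image
#'
#' Gaussian-smooths the image, finds local maxima above `threshold`, and
#' suppresses non-maximal detections within a radius of `sigma` pixels
#' (two spots closer than `sigma` therefore merge into one detection).
#' A generic replacement for interactive spot-counting tools.
#'
#' @param image 2D numeric matrix.
#' @param sigma expected spot scale (px); also the suppression radius.
#' @param threshold intensity threshold on the smoothed image.
#' @param pixel_size um per pixel; with `origin_px` maps detections to um.
#' @param origin_px pixel coordinates `(col, row)` mapping to (0, 0) um;
#'   default image center.
#' @return n x 2 matrix of detection coordinates (um; x right, y up).
#' @export
detect_spots <- function(image, sigma = 2, threshold, pixel_size = 1,
                         origin_px = NULL) {
  image <- as.matrix(image)
  nr <- nrow(image); nc <- ncol(image)
  k <- max(3L, 2L * ceiling(2 * sigma) + 1L)
  sm <- box_blur(image, min(k, min(nr, nc) - (1 - min(nr, nc) %% 2)))
  nb <- neighbor_stack(sm)
  nb_max <- suppressWarnings(apply(nb, 1L, max, na.rm = TRUE))
  smv <- as.vector(sm)
  cand <- which(smv >= threshold & smv >= nb_max)
  if (!length(cand)) return(matrix(numeric(0), ncol = 2,
                                   dimnames = list(NULL, c("x_um", "y_um"))))
  iy <- (cand - 1L) %% nr + 1L
  ix <- (cand - 1L) %/% nr + 1L
  ord <- order(-smv[cand])
  keep <- logical(length(cand))
  for (k2 in ord) {
    if (any(keep & sqrt((ix - ix[k2])^2 + (iy - iy[k2])^2) < sigma)) next
    keep[k2] <- TRUE
  }
  ix <- ix[keep]; iy <- iy[keep]
  # centroid refinement over a 3x3 neighborhood of the smoothed image
  cx <- cy <- numeric(length(ix))
  for (i in seq_along(ix)) {
    rx <- max(1L, ix[i] - 1L):min(nc, ix[i] + 1L)
    ry <- max(1L, iy[i] - 1L):min(nr, iy[i] + 1L)
    wt <- sm[ry, rx, drop = FALSE]
    wt <- pmax(wt - min(wt), 0)
    tot <- sum(wt)
    if (tot > 0) {
      cx[i] <- sum(outer(rep(1, length(ry)), rx) * wt) / tot
      cy[i] <- sum(outer(ry, rep(1, length(rx))) * wt) / tot
    } else { cx[i] <- ix[i]; cy[i] <- iy[i] }
  }
  if (is.null(origin_px)) origin_px <- c((nc + 1) / 2, (nr + 1) / 2)
  cbind(x_um = (cx - origin_px[1]) * pixel_size,
        y_um = (origin_px[2] - cy) * pixel_size)
}

#' Per-square labeled fractions on the counting grid
#'
#' Counts total and labeled points in each grid square and computes the
#' per-square labeled fraction. Labeled points are matched to the totals
#' by nearest neighbor within `match_tol` (channel-registration slack);
#' unmatched labeled points are ignored. The summary statistic is the
#' mean of per-square fractions ("count per square, then average"), with
#' empty squares excluded from the mean; the pooled ratio is also
#' reported.
#'
#' @param all_points n x 2 matrix of all-nuclei coordinates (um).
#' @param labeled_points m x 2 matrix of labeled-nuclei coordinates (um).
#' @param grid a [place_grid()] result.
#' @param match_tol nearest-neighbor matching tolerance (um); `Inf`
#'   counts labeled points directly per square.
#' @return the `quant_grid` with `squares` gaining `total`, `labeled`,
#'   `fraction`, plus `mean_fraction`, `pooled_fraction`, and
#'   `empty_squares`.
#' @export
labeled_fraction <- function(all_points, labeled_points, grid,
                             match_tol = Inf) {
  stopifnot(inherits(grid, "quant_grid"))
  if (is.null(dim(all_points))) all_points <- matrix(all_points, ncol = 2)
  if (is.null(dim(labeled_points))) {
    labeled_points <- matrix(labeled_points, ncol = 2)
  }
  if (nrow(labeled_points) && is.finite(match_tol) && nrow(all_points)) {
    keep <- vapply(seq_len(nrow(labeled_points)), function(i) {
      d2 <- (all_points[, 1] - labeled_points[i, 1])^2 +
        (all_points[, 2] - labeled_points[i, 2])^2
      min(d2) <= match_tol^2
    }, logical(1))
    labeled_points <- labeled_points[keep, , drop = FALSE]
  }
  sq <- grid$squares
  in_square <- function(pts, s) {
    if (!nrow(pts)) return(0L)
    sum(pts[, 1] >= s$xmin & pts[, 1] < s$xmax &
        pts[, 2] >= s$ymin & pts[, 2] < s$ymax)
  }
  sq$total <- vapply(seq_len(nrow(sq)), function(i) in_square(all_points,
                                                              sq[i, ]),
                     integer(1))
  sq$labeled <- vapply(seq_len(nrow(sq)), function(i) {
    in_square(labeled_points, sq[i, ])
  }, integer(1))
  sq$fraction <- ifelse(sq$total > 0, sq$labeled / sq$total, NA_real_)
  grid$squares <- sq
  grid$empty_squares <- sum(sq$total == 0)
  grid$mean_fraction <- mean(sq$fraction, na.rm = TRUE)
  grid$pooled_fraction <- if (sum(sq$total) > 0) {
    sum(sq$labeled) / sum(sq$total)
  } else NA_real_
  grid
}

#' Write a quantified grid as delimited text
#'
#' @param grid a quantified `quant_grid`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_quant_grid <- function(grid, path) {
  stopifnot(inherits(grid, "quant_grid"))
  utils::write.csv(grid$squares, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
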