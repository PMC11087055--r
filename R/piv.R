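# Two-pass windowed cross-correlation PIV.
#
# Displacements are reported as the shift of frame_b relative to frame_a,
# in pixels, with dx along image columns and dy along image rows (row
# index increases downward). Correlation is computed in the frequency
# domain on mean-subtracted, variance-normalized interrogation windows;
# the integer peak is refined per axis by a three-point Gaussian fit
# (parabolic fallback when a neighbor is non-positive).

#' PIV parameters
#'
#' @param pass1_window first-pass interrogation window (px; power of two,
#'   >= 8). The analysis default is 64 px with 50% overlap.
#' @param pass2_window second-pass window (px; power of two, <=
#'   `pass1_window`). Default 32 px with 50% overlap.
#' @param overlap_fraction window overlap in \[0, 1).
#' @param highpass_kernel preprocessing high-pass kernel size (px, odd);
#'   `NULL` disables preprocessing.
#' @param outlier_threshold normalized-median-test threshold.
#' @param median_eps normalized-median-test noise floor (px).
#' @param max_displacement absolute displacement cap (px); `NULL` uses
#'   half the interrogation window.
#' @param smoothing logical: apply a final 3x3 smoothing of the field.
#' @param subpixel_method `"three-point-gaussian"` (the only method).
#' @return an object of class `piv_params`.
#' @export
piv_params <- function(pass1_window = 64L, pass2_window = 32L,
                       overlap_fraction = 0.5, highpass_kernel = 15L,
                       outlier_threshold = 2.0, median_eps = 0.1,
                       max_displacement = NULL, smoothing = TRUE,
                       subpixel_method = "three-point-gaussian") {
  if (!is_power_of_two(pass1_window) || pass1_window < 8 ||
      !is_power_of_two(pass2_window) || pass2_window < 8) {
    stop("interrogation windows must be powers of two >= 8", call. = FALSE)
  }
  if (pass2_window > pass1_window) {
    stop("`pass2_window` must be <= `pass1_window`", call. = FALSE)
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("`overlap_fraction` must be in [0, 1)", call. = FALSE)
  }
  subpixel_method <- match.arg(subpixel_method, "three-point-gaussian")
  structure(list(pass1_window = as.integer(pass1_window),
                 pass2_window = as.integer(pass2_window),
                 overlap_fraction = overlap_fraction,
                 highpass_kernel = highpass_kernel,
                 outlier_threshold = outlier_threshold,
                 median_eps = median_eps,
                 max_displacement = max_displacement,
                 smoothing = isTRUE(smoothing),
                 subpixel_method = subpixel_method),
            class = "piv_params")
}

#' High-pass filter an image to emphasize particles
#'
#' Subtracts a local moving-average (box) low-pass of size `kernel` from
#' the image and clips negative values at zero, suppressing slowly varying
#' background while preserving bright spots.
#'
#' @param image numeric matrix.
#' @param kernel box size (px), odd, >= 3, smaller than the image.
#' @return filtered matrix (same shape, non-negative).
#' @export
highpass_filter <- function(image, kernel = 15L) {
  image <- as.matrix(image)
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L) {
    stop("`kernel` must be odd and >= 3", call. = FALSE)
  }
  if (kernel >= min(dim(image))) {
    stop("`kernel` must be smaller than the image", call. = FALSE)
  }
  pmax(image - box_blur(image, kernel), 0)
}

# ---- batched correlation machinery ----------------------------------------

# Extract N windows of size w x w from `frame` at 0-based top-left corners
# (tl_row, tl_col); returns a (w*w) x N matrix, column-major per window.
extract_windows <- function(frame, tl_row, tl_col, w) {
  nr <- nrow(frame)
  block <- as.vector(outer(seq_len(w) - 1L, (seq_len(w) - 1L) * nr, "+"))
  start <- tl_row + nr * tl_col
  dim(frame) <- NULL
  matrix(frame[outer(block, start, "+") + 1L], nrow = w * w)
}

# Normalize windows to zero mean, unit variance; zero-variance windows are
# zeroed and flagged.
normalize_windows <- function(W) {
  m <- nrow(W)
  mu <- colMeans(W)
  W <- W - rep(mu, each = m)
  sd2 <- colMeans(W^2)
  ok <- sd2 > 1e-12
  scl <- ifelse(ok, 1 / sqrt(pmax(sd2, 1e-300)), 0)
  list(W = W * rep(scl, each = m), ok = ok)
}

# Tukey (tapered-cosine) interrogation-window weighting, plus the inverse
# of the taper's circular autocorrelation per lag. Weighting the windows
# suppresses the bias from particles truncated at window edges; dividing
# the correlation plane by the taper autocorrelation removes the bias the
# weighting itself would introduce. The divisor is floored to avoid noise
# amplification at extreme lags.
corr_taper <- function(w, alpha = 0.5) {
  t <- (seq_len(w) - 1) / (w - 1)
  e <- alpha / 2
  t1 <- pmin(t / e, 1)
  t2 <- pmin((1 - t) / e, 1)
  win <- (0.5 * (1 - cos(pi * t1))) * (0.5 * (1 - cos(pi * t2)))
  tw <- as.vector(outer(win, win))
  f <- stats::fft(matrix(tw, w, w))
  Rw <- Re(stats::fft(Conj(f) * f, inverse = TRUE)) / (w * w)
  Rw <- pmax(Rw, 0.1 * max(Rw))
  list(tw = tw, rw_inv = as.vector(max(Rw) / Rw))
}

# Cross-correlate paired, pre-normalized window stacks. Returns integer and
# sub-pixel lags (dy = row lag, dx = col lag), peak value and (optionally)
# peak ratio. Both real window stacks ride through a single complex FFT
# (packed as a + ib); the cross-spectrum is recovered from the transform's
# Hermitian structure.
correlate_batch <- function(Wa, Wb, w, taper = corr_taper(w),
                            compute_ratio = FALSE) {
  n <- ncol(Wa)
  Z <- (Wa + (0 + 1i) * Wb) * taper$tw
  # forward 2D FFT, ending in transposed layout (one aperm instead of two)
  dim(Z) <- c(w, w * n)
  Z <- stats::mvfft(Z)
  dim(Z) <- c(w, w, n)
  Z <- aperm(Z, c(2L, 1L, 3L))
  dim(Z) <- c(w, w * n)
  Z <- stats::mvfft(Z)
  dim(Z) <- c(w * w, n)
  # unpack: F(a) = (Z + conj(Z(-k)))/2, F(b) = (Z - conj(Z(-k)))/(2i)
  ij <- 0:(w * w - 1)
  ci <- ij %% w; ri <- ij %/% w
  neg <- ((w - ci) %% w) + w * ((w - ri) %% w) + 1L
  Zr <- Conj(Z[neg, , drop = FALSE])
  S <- Conj(0.5 * (Z + Zr)) * ((0 - 0.5i) * (Z - Zr))
  # inverse 2D FFT back to normal layout
  dim(S) <- c(w, w * n)
  S <- stats::mvfft(S, inverse = TRUE)
  dim(S) <- c(w, w, n)
  S <- aperm(S, c(2L, 1L, 3L))
  dim(S) <- c(w, w * n)
  S <- stats::mvfft(S, inverse = TRUE)
  C <- Re(S) / (w * w) / (w * w)
  dim(C) <- c(w * w, n)
  C <- C * taper$rw_inv
  # integer peak per window
  idx <- vapply(seq_len(n), function(j) which.max(C[, j]), integer(1))
  i0 <- (idx - 1L) %% w + 1L
  j0 <- (idx - 1L) %/% w + 1L
  sel <- function(i, j) C[cbind((j - 1L) * w + i, seq_len(n))]
  wrap_i <- function(i) (i - 1L) %% w + 1L
  c0 <- sel(i0, j0)
  cym <- sel(wrap_i(i0 - 1L), j0); cyp <- sel(wrap_i(i0 + 1L), j0)
  cxm <- sel(i0, wrap_i(j0 - 1L)); cxp <- sel(i0, wrap_i(j0 + 1L))

  subpixel <- function(cm, cc, cp) {
    d <- numeric(length(cc))
    g <- cm > 0 & cp > 0 & cc > 0 & cc >= cm & cc >= cp
    den <- log(cm[g]) + log(cp[g]) - 2 * log(cc[g])
    dg <- ifelse(abs(den) > 1e-12, 0.5 * (log(cm[g]) - log(cp[g])) / den, 0)
    d[g] <- dg
    p <- !g
    denp <- cm[p] + cp[p] - 2 * cc[p]
    d[p] <- ifelse(abs(denp) > 1e-12, 0.5 * (cm[p] - cp[p]) / denp, 0)
    pmin(pmax(d, -1), 1)
  }
  ddy <- subpixel(cym, c0, cyp)
  ddx <- subpixel(cxm, c0, cxp)

  # peak ratio: primary peak over the best value outside its 3x3 block
  if (compute_ratio) {
    C2 <- C
    for (di in -1:1) for (dj in -1:1) {
      C2[cbind((wrap_i(j0 + dj) - 1L) * w + wrap_i(i0 + di), seq_len(n))] <- -Inf
    }
    second <- apply(C2, 2L, max)
    ratio <- ifelse(second > 0, c0 / second, Inf)
  } else {
    ratio <- rep(NA_real_, n)
  }

  list(dy_int = wrap_lag(i0 - 1L, w), dx_int = wrap_lag(j0 - 1L, w),
       dy = wrap_lag(i0 - 1L, w) + ddy, dx = wrap_lag(j0 - 1L, w) + ddx,
       peak = c0, ratio = pmax(ratio, 1))
}

#' Cross-correlate one window pair
#'
#' Frequency-domain normalized cross-correlation of two equally sized
#' square windows, with integer peak location and three-point Gaussian
#' sub-pixel refinement per axis. The offset is the displacement of
#' `window_b` relative to `window_a` in `(dx, dy)` pixels.
#'
#' @param window_a,window_b square numeric matrices of equal size.
#' @return an object of class `correlation_peak` with `integer_offset`,
#'   `subpixel_offset`, `peak_value`, `peak_ratio`, `valid`.
#' @export
#' @examples
#' w <- render_spots(cbind(c(10, 22), c(14, 8)), c(32, 32), sigma = 2)
#' correlate_windows(w, w)$subpixel_offset
correlate_windows <- function(window_a, window_b) {
  window_a <- as.matrix(window_a); window_b <- as.matrix(window_b)
  if (!all(dim(window_a) == dim(window_b)) ||
      nrow(window_a) != ncol(window_a)) {
    stop("windows must be square and of identical shape", call. = FALSE)
  }
  w <- nrow(window_a)
  na <- normalize_windows(matrix(window_a, ncol = 1))
  nb <- normalize_windows(matrix(window_b, ncol = 1))
  ok <- na$ok & nb$ok
  if (!ok) {
    return(structure(list(integer_offset = c(NA_real_, NA_real_),
                          subpixel_offset = c(NA_real_, NA_real_),
                          peak_value = NA_real_, peak_ratio = NA_real_,
                          valid = FALSE),
                     class = "correlation_peak"))
  }
  r <- correlate_batch(na$W, nb$W, w, compute_ratio = TRUE)
  structure(list(integer_offset = c(r$dx_int, r$dy_int),
                 subpixel_offset = c(r$dx, r$dy),
                 peak_value = r$peak, peak_ratio = r$ratio, valid = TRUE),
            class = "correlation_peak")
}

#' Single PIV pass over a frame pair
#'
#' Partitions the frames into square interrogation windows on a regular
#' grid (spacing `window * (1 - overlap)`) and cross-correlates each pair.
#' With a `predictor` field (from a coarser pass), the second frame's
#' windows are offset by the integer-rounded predictor displacement at
#' each node (discrete window offsetting) and the recovered residual is
#' added back.
#'
#' @param frame_a,frame_b numeric matrices of identical shape.
#' @param window interrogation window size (px).
#' @param overlap overlap fraction in \[0, 1).
#' @param predictor optional `velocity_field` (px/frame, image
#'   coordinates) used for window offsetting.
#' @return a `velocity_field` in `px_per_frame` units on the pass grid
#'   (image coordinates: y is the row coordinate, increasing downward).
#' @export
piv_pass <- function(frame_a, frame_b, window = 64L, overlap = 0.5,
                     predictor = NULL) {
  frame_a <- as.matrix(frame_a); frame_b <- as.matrix(frame_b)
  if (!all(dim(frame_a) == dim(frame_b))) {
    stop("frames must have the same shape", call. = FALSE)
  }
  w <- as.integer(window)
  nr <- nrow(frame_a); nc <- ncol(frame_a)
  if (w > min(nr, nc)) stop("window larger than image", call. = FALSE)
  s <- max(1L, as.integer(round(w * (1 - overlap))))
  tl_r <- seq.int(0L, nr - w, by = s)
  tl_c <- seq.int(0L, nc - w, by = s)
  ny <- length(tl_r); nx <- length(tl_c)
  # node centers in pixel coordinates
  yc <- tl_r + (w + 1) / 2
  xc <- tl_c + (w + 1) / 2
  TLr <- rep(tl_r, times = nx)
  TLc <- rep(tl_c, each = ny)

  # integer predictor shift per node
  if (!is.null(predictor)) {
    pu <- round(bilinear(predictor$x, predictor$y, predictor$u,
                         rep(xc, each = ny), rep(yc, times = nx)))
    pv <- round(bilinear(predictor$x, predictor$y, predictor$v,
                         rep(xc, each = ny), rep(yc, times = nx)))
    # clamp shifted windows into the image
    sr <- pmin(pmax(TLr + pv, 0L), nr - w) - TLr
    sc <- pmin(pmax(TLc + pu, 0L), nc - w) - TLc
  } else {
    sr <- sc <- rep(0L, ny * nx)
  }

  Wa <- extract_windows(frame_a, TLr, TLc, w)
  Wb <- extract_windows(frame_b, TLr + sr, TLc + sc, w)
  na <- normalize_windows(Wa)
  nb <- normalize_windows(Wb)
  res <- correlate_batch(na$W, nb$W, w)
  ok <- na$ok & nb$ok

  u <- matrix(res$dx + sc, ny, nx)
  v <- matrix(res$dy + sr, ny, nx)
  u[!ok] <- 0; v[!ok] <- 0
  velocity_field(xc, yc, u, v, valid = matrix(ok, ny, nx),
                 units = "px_per_frame")
}

# ---- vector validation ----------------------------------------------------

# Row-wise median of an N x 8 neighbor matrix with NAs, via a vectorized
# odd-even transposition sort (NA -> +Inf).
rowmed_k <- function(M) {
  k <- ncol(M)
  nv <- rowSums(!is.na(M))
  M[is.na(M)] <- Inf
  for (pass in seq_len(k)) {
    start <- if (pass %% 2L == 1L) 1L else 2L
    js <- seq.int(start, k - 1L, by = 2L)
    for (j in js) {
      a <- pmin(M[, j], M[, j + 1L])
      b <- pmax(M[, j], M[, j + 1L])
      M[, j] <- a; M[, j + 1L] <- b
    }
  }
  lo <- (nv + 1L) %/% 2L
  hi <- (nv + 2L) %/% 2L
  out <- rep(NA_real_, nrow(M))
  has <- nv > 0L
  i <- which(has)
  out[i] <- (M[cbind(i, lo[i])] + M[cbind(i, hi[i])]) / 2
  out
}

# Stack the 8-neighborhood of a matrix into an N x 8 matrix (NA at borders
# or where the neighbor is excluded by `mask`).
neighbor_stack <- function(m, mask = NULL) {
  ny <- nrow(m); nx <- ncol(m)
  if (!is.null(mask)) m[!mask] <- NA_real_
  p <- matrix(NA_real_, ny + 2L, nx + 2L)
  p[2:(ny + 1L), 2:(nx + 1L)] <- m
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  out <- matrix(NA_real_, ny * nx, 8L)
  for (k in seq_along(shifts)) {
    dr <- shifts[[k]][1]; dc <- shifts[[k]][2]
    out[, k] <- as.vector(p[(2:(ny + 1L)) + dr, (2:(nx + 1L)) + dc])
  }
  out
}

# Iterative neighbor averaging (Laplace fill) of nodes flagged FALSE in
# `keep`, seeded with the mean of kept values.
laplace_fill <- function(m, keep, tol = 1e-6, max_iter = 500L) {
  if (all(keep)) return(m)
  fill0 <- mean(m[keep])
  m[!keep] <- fill0
  ny <- nrow(m); nx <- ncol(m)
  scale <- max(abs(m[keep]), 1e-12)
  for (it in seq_len(max_iter)) {
    p <- pad_replicate(m, 1L)
    nb <- (p[1:ny, 2:(nx + 1L)] + p[3:(ny + 2L), 2:(nx + 1L)] +
           p[2:(ny + 1L), 1:nx] + p[2:(ny + 1L), 3:(nx + 2L)]) / 4
    new <- ifelse(keep, m, nb)
    delta <- max(abs(new - m))
    m <- new
    if (delta <= tol * scale) break
  }
  m
}

#' Validate, interpolate and smooth a PIV vector field
#'
#' Applies (i) an absolute displacement cap and a normalized median test
#' against the 3x3 neighborhood, marking failing nodes invalid; (ii)
#' iterative neighbor-averaging interpolation of invalid nodes (flagged
#' `interpolated`); and (iii) optionally a 3x3 smoothing of the final
#' field.
#'
#' @param field a `velocity_field` (any units).
#' @param params a [piv_params()]; uses `outlier_threshold`, `median_eps`,
#'   `max_displacement` and `smoothing`.
#' @return the validated `velocity_field`.
#' @export
validate_vectors <- function(field, params = piv_params()) {
  stopifnot(inherits(field, "velocity_field"))
  ny <- length(field$y); nx <- length(field$x)
  if (ny < 3L || nx < 3L) stop("field must have at least 3x3 nodes",
                               call. = FALSE)
  u <- field$u; v <- field$v
  good <- field$valid

  cap <- params$max_displacement
  if (!is.null(cap) && is.finite(cap)) {
    good <- good & sqrt(u^2 + v^2) <= cap
  }

  # normalized median test per component on the current good set
  for (comp in list(u, v)) {
    nb <- neighbor_stack(comp, mask = good)
    med <- rowmed_k(nb)
    resid <- rowmed_k(abs(nb - med))
    r <- abs(as.vector(comp) - med) / (resid + params$median_eps)
    fail <- !is.na(r) & r > params$outlier_threshold
    good <- good & !matrix(fail, ny, nx)
  }

  frac_bad <- 1 - mean(good)
  if (all(!good)) stop("all vectors invalid: no basis for interpolation",
                       call. = FALSE)
  if (frac_bad > 0.5) {
    warning(sprintf("%.0f%% of vectors marked invalid", 100 * frac_bad),
            call. = FALSE)
  }

  u <- laplace_fill(u, good)
  v <- laplace_fill(v, good)
  interp <- !good

  if (params$smoothing) {
    u <- box_blur(u, 3L)
    v <- box_blur(v, 3L)
  }
  velocity_field(field$x, field$y, u, v, valid = good | interp,
                 interpolated = interp, units = field$units, t = field$t)
}

#' Two-pass PIV on a frame pair
#'
#' Runs a coarse first pass, validates it, and feeds it as a discrete
#' window-offsetting predictor into a finer second pass, which is
#' validated in turn. The returned grid is the second-pass grid, in
#' `px_per_frame` units and image coordinates.
#'
#' @param frame_a,frame_b numeric matrices (consecutive frames).
#' @param params a [piv_params()].
#' @param preprocess apply [highpass_filter()] with
#'   `params$highpass_kernel` to both frames first.
#' @return a `velocity_field`.
#' @export
two_pass_piv <- function(frame_a, frame_b, params = piv_params(),
                         preprocess = TRUE) {
  stopifnot(inherits(params, "piv_params"))
  if (preprocess && !is.null(params$highpass_kernel)) {
    frame_a <- highpass_filter(frame_a, params$highpass_kernel)
    frame_b <- highpass_filter(frame_b, params$highpass_kernel)
  }
  p1 <- piv_pass(frame_a, frame_b, params$pass1_window,
                 params$overlap_fraction)
  par1 <- params
  par1$max_displacement <- params$max_displacement %||% (params$pass1_window / 2)
  par1$smoothing <- TRUE   # smooth predictor stabilizes offsetting
  p1v <- validate_vectors(p1, par1)

  p2 <- piv_pass(frame_a, frame_b, params$pass2_window,
                 params$overlap_fraction, predictor = p1v)
  par2 <- params
  par2$max_displacement <- params$max_displacement %||%
    (params$pass1_window / 2)
  validate_vectors(p2, par2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
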