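# Internal helpers shared across modules.

#' Evaluate an expression with a temporarily fixed RNG state
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Smoothstep ramp: 0 below 0, 1 above 1, C1-continuous cubic in between.
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# Cosine half-ramp from 1 (u = 0) down to 0 (u = 1), clamped outside.
cos_down <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  0.5 * (1 + cos(pi * u))
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

is_power_of_two <- function(n) {
  n == as.integer(n) && n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}

#' Bilinear interpolation on a regular grid
#'
#' Values outside the grid hull are clamped to the border value.
#'
#' @param gx,gy ascending grid node coordinates.
#' @param z matrix of values, `length(gy)` rows x `length(gx)` columns.
#' @param x,y query coordinates (vectors of equal length).
#' @return numeric vector of interpolated values.
#' @keywords internal
#' @noRd
bilinear <- function(gx, gy, z, x, y) {
  nx <- length(gx); ny <- length(gy)
  if (nx == 1L && ny == 1L) return(rep(z[1L], length(x)))
  if (nx == 1L) {
    iy <- findInterval(y, gy, all.inside = TRUE)
    ty <- pmin(pmax((y - gy[iy]) / (gy[iy + 1L] - gy[iy]), 0), 1)
    return((1 - ty) * z[iy, 1L] + ty * z[iy + 1L, 1L])
  }
  if (ny == 1L) {
    ix <- findInterval(x, gx, all.inside = TRUE)
    tx <- pmin(pmax((x - gx[ix]) / (gx[ix + 1L] - gx[ix]), 0), 1)
    return((1 - tx) * z[1L, ix] + tx * z[1L, ix + 1L])
  }
  ix <- findInterval(x, gx, all.inside = TRUE)
  iy <- findInterval(y, gy, all.inside = TRUE)
  x1 <- gx[ix]; x2 <- gx[ix + 1L]
  y1 <- gy[iy]; y2 <- gy[iy + 1L]
  tx <- pmin(pmax((x - x1) / (x2 - x1), 0), 1)
  ty <- pmin(pmax((y - y1) / (y2 - y1), 0), 1)
  z11 <- z[cbind(iy, ix)]
  z12 <- z[cbind(iy, ix + 1L)]
  z21 <- z[cbind(iy + 1L, ix)]
  z22 <- z[cbind(iy + 1L, ix + 1L)]
  (1 - ty) * ((1 - tx) * z11 + tx * z12) + ty * ((1 - tx) * z21 + tx * z22)
}

# Replicate-pad a matrix by `k` rows/cols on every side.
pad_replicate <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, k), seq_len(nr), rep(nr, k))
  ci <- c(rep(1L, k), seq_len(nc), rep(nc, k))
  m[ri, ci, drop = FALSE]
}

# Separable moving-average blur with replicate padding (kernel size k,
# odd), via a summed-area table.
box_blur <- function(m, k) {
  k <- as.integer(k)
  if (k <= 1L) return(m)
  h <- (k - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  p <- pad_replicate(m, h)
  s <- apply(p, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  s0 <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  s0[-1L, -1L] <- s
  ri <- seq_len(nr); ci <- seq_len(nc)
  (s0[ri + k, ci + k] - s0[ri, ci + k] - s0[ri + k, ci] + s0[ri, ci]) / (k * k)
}

# Sum `w` into groups given by positive integer codes `idx` (radix sort +
# grouped cumsum); returns list(index = unique codes, sum = group sums).
group_sum <- function(w, idx) {
  o <- sort.list(idx, method = "radix")
  ls <- idx[o]
  ws <- w[o]
  n <- length(ls)
  new <- c(TRUE, ls[-1L] != ls[-n])
  cs <- cumsum(ws)
  ends <- which(c(new[-1L], TRUE))
  sums <- cs[ends] - c(0, cs[ends[-length(ends)]])
  list(index = ls[new], sum = sums)
}

# Batched 2D FFT of N stacked w x w windows held as a (w*w) x N matrix
# (column-major within each window). inverse = TRUE gives the unscaled
# inverse transform (divide by w^2 yourself if needed).
fft2_batch <- function(W, w, inverse = FALSE) {
  n <- length(W) / (w * w)
  dim(W) <- c(w, w * n)
  M <- stats::mvfft(W, inverse = inverse)
  dim(M) <- c(w, w, n)
  M <- aperm(M, c(2L, 1L, 3L))
  dim(M) <- c(w, w * n)
  M <- stats::mvfft(M, inverse = inverse)
  dim(M) <- c(w, w, n)
  M <- aperm(M, c(2L, 1L, 3L))
  dim(M) <- c(w * w, n)
  M
}

# Wrap circular-correlation lags: indices 1..w map to lags 0..w-1, with
# lags above w/2 aliased to negative.
wrap_lag <- function(idx0, w) {
  ifelse(idx0 > w / 2, idx0 - w, idx0)
}

format_um <- function(x) sprintf("%.1f μm", x)
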