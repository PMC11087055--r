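# Shared fixtures and independent oracles, all built in code.

# Analytic velocity field on a regular grid; fn(x, y) returns list(u, v).
field_from_fn <- function(fn, gx = seq(-1000, 1000, by = 50),
                          gy = gx, units = "um_per_s", t = 0) {
  X <- outer(rep(1, length(gy)), gx)
  Y <- outer(gy, rep(1, length(gx)))
  uv <- fn(X, Y)
  velocity_field(gx, gy, uv$u, uv$v, units = units, t = t)
}

rigid_rotation_field <- function(omega, ...) {
  field_from_fn(function(x, y) list(u = -omega * y, v = omega * x), ...)
}

uniform_field <- function(u0, v0, ...) {
  field_from_fn(function(x, y) list(u = x * 0 + u0, v = y * 0 + v0), ...)
}

# Evaluate a flow model on a grid as a velocity_field.
model_field <- function(model, t, gx = seq(-1400, 1400, by = 40), gy = gx) {
  pts <- cbind(rep(gx, each = length(gy)), rep(gy, times = length(gx)))
  V <- velocity_at(model, pts, t)
  velocity_field(gx, gy,
                 matrix(V[, 1], length(gy), length(gx)),
                 matrix(V[, 2], length(gy), length(gx)),
                 units = "um_per_s", t = t)
}

# Frame pair related by a uniform (possibly sub-pixel) translation,
# rendered from the same particle set.
translated_pair <- function(d, n_particles = 400, shape = c(256L, 256L),
                            sigma = 2, seed = 1) {
  pos <- polonaise:::with_seed(seed, cbind(
    stats::runif(n_particles, 12, shape[2] - 12),
    stats::runif(n_particles, 12, shape[1] - 12)))
  list(a = render_spots(pos, shape, sigma = sigma),
       b = render_spots(pos + matrix(rep(d, each = n_particles), ncol = 2),
                        shape, sigma = sigma),
       positions = pos)
}

# Frame pair related by a rigid rotation by angle theta about the image
# center; returns the analytic displacement at a (col, row) node.
rotated_pair <- function(theta, n_particles = 1200, shape = c(256L, 256L),
                         sigma = 2, seed = 2) {
  ctr <- (shape[c(2, 1)] + 1) / 2
  pos <- polonaise:::with_seed(seed, cbind(
    stats::runif(n_particles, 6, shape[2] - 6),
    stats::runif(n_particles, 6, shape[1] - 6)))
  rel <- sweep(pos, 2, ctr)
  rot <- cbind(cos(theta) * rel[, 1] - sin(theta) * rel[, 2],
               sin(theta) * rel[, 1] + cos(theta) * rel[, 2])
  pos2 <- sweep(rot, 2, ctr, "+")
  disp_at <- function(x, y) {
    rx <- x - ctr[1]; ry <- y - ctr[2]
    cbind(cos(theta) * rx - sin(theta) * ry - rx,
          sin(theta) * rx + cos(theta) * ry - ry)
  }
  list(a = render_spots(pos, shape, sigma = sigma),
       b = render_spots(pos2, shape, sigma = sigma),
       disp_at = disp_at)
}

# Independent sub-pixel oracle: argmax of the cross-correlation plane
# upsampled `f`-fold by zero-padding the cross-spectrum (Nyquist bin
# dropped). Returns c(dx, dy) at 1/f px resolution.
upsampled_peak_oracle <- function(wa, wb, f = 16L) {
  w <- nrow(wa)
  S <- Conj(stats::fft(wa - mean(wa))) * stats::fft(wb - mean(wb))
  W <- w * f
  h <- w %/% 2L
  P <- matrix(0 + 0i, W, W)
  pos <- 1:h                    # frequencies 0 .. h-1
  neg_src <- (h + 2L):w         # frequencies -(h-1) .. -1
  neg_dst <- (W - h + 2L):W
  P[pos, pos] <- S[pos, pos]
  P[pos, neg_dst] <- S[pos, neg_src]
  P[neg_dst, pos] <- S[neg_src, pos]
  P[neg_dst, neg_dst] <- S[neg_src, neg_src]
  C <- Re(stats::fft(P, inverse = TRUE))
  pk <- which.max(C)
  i <- (pk - 1L) %% W; j <- (pk - 1L) %/% W
  lag <- function(k) if (k > W / 2) (k - W) / f else k / f
  c(dx = lag(j), dy = lag(i))
}

# Fine-step advection oracle: RK4 with `refine` substeps per frame
# interval, using only velocity_at.
oracle_advect <- function(model, p0, times, refine = 100L) {
  pos <- matrix(p0, ncol = 2)
  out <- matrix(NA_real_, length(times), 2)
  out[1, ] <- pos
  for (k in seq_len(length(times) - 1L)) {
    dt <- (times[k + 1L] - times[k]) / refine
    t <- times[k]
    for (s in seq_len(refine)) {
      k1 <- velocity_at(model, pos, t)
      k2 <- velocity_at(model, pos + dt / 2 * k1, t + dt / 2)
      k3 <- velocity_at(model, pos + dt / 2 * k2, t + dt / 2)
      k4 <- velocity_at(model, pos + dt * k3, t + dt)
      pos <- pos + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + dt
    }
    out[k + 1L, ] <- pos
  }
  out
}
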