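# Two-pass cross-correlation PIV: filtering, correlation, passes,
# validation, calibration.

test_that("highpass_filter suppresses background and keeps spot positions", {
  expect_equal(highpass_filter(matrix(5, 32, 32), 5), matrix(0, 32, 32))
  img <- matrix(0, 33, 33); img[17, 17] <- 10
  hp <- highpass_filter(img, 5)
  expect_equal(which.max(hp), which.max(img))
  # spots on a smooth gradient: argmax positions preserved within a pixel
  grad <- outer(seq(0, 60, length.out = 128), seq(0, 40, length.out = 128),
                "+")
  pos <- cbind(c(30, 80, 100), c(40, 90, 25))
  spots <- render_spots(pos, c(128, 128), sigma = 2, amplitude = 50)
  hp2 <- highpass_filter(spots + grad, 15)
  for (i in seq_len(nrow(pos))) {
    patch <- hp2[pos[i, 2] + (-3:3), pos[i, 1] + (-3:3)]
    pk <- which(patch == max(patch), arr.ind = TRUE)
    expect_lte(max(abs(pk[1, ] - 4)), 0.5)
  }
  expect_error(highpass_filter(matrix(0, 8, 8), 9), "smaller than the image")
  expect_error(highpass_filter(matrix(0, 32, 32), 4), "odd")
})

test_that("correlate_windows recovers integer and sub-pixel shifts", {
  w <- polonaise:::with_seed(3, render_spots(
    cbind(runif(15, 4, 60), runif(15, 4, 60)), c(64, 64), sigma = 2))
  same <- correlate_windows(w, w)
  expect_equal(same$integer_offset, c(0, 0))
  expect_equal(same$subpixel_offset, c(0, 0), tolerance = 1e-9)
  expect_gte(same$peak_ratio, 1)
  # circular shift by (5, -3): rows by -3 wraps content down... build
  # explicitly: b[r, c] = a[r - dy, c - dx] (content moved by +dy, +dx)
  shift_circ <- function(m, dy, dx) {
    n <- nrow(m)
    m[((seq_len(n) - 1 - dy) %% n) + 1, ((seq_len(n) - 1 - dx) %% n) + 1]
  }
  ws <- shift_circ(w, -3, 5)
  p <- correlate_windows(w, ws)
  expect_equal(p$integer_offset, c(5, -3))
  # zero-variance window flagged, not an exception
  z <- correlate_windows(matrix(1, 32, 32), matrix(1, 32, 32))
  expect_false(z$valid)
  expect_true(is.na(z$peak_value))
})

test_that("sub-pixel offsets agree with an upsampled-correlation oracle", {
  d <- c(2.40, 0)
  pr <- translated_pair(d, n_particles = 20, shape = c(64L, 64L), seed = 5)
  p <- correlate_windows(pr$a, pr$b)
  expect_equal(p$subpixel_offset[1], 2.40, tolerance = 0.1)
  orc <- upsampled_peak_oracle(pr$a, pr$b, f = 16L)
  expect_equal(p$subpixel_offset[1], unname(orc["dx"]), tolerance = 0.1)
  expect_equal(p$subpixel_offset[2], unname(orc["dy"]), tolerance = 0.1)
})

test_that("piv_pass recovers rigid translations and rotations on its grid", {
  pr0 <- translated_pair(c(0, 0))
  f0 <- piv_pass(pr0$a, pr0$a, 64, 0.5)
  expect_true(all(f0$valid))
  expect_equal(max(abs(f0$u)), 0, tolerance = 1e-9)
  expect_equal(max(abs(f0$v)), 0, tolerance = 1e-9)
  # grid geometry: spacing window * (1 - overlap)
  expect_equal(diff(f0$x)[1], 32)

  pr <- translated_pair(c(4, 2))
  f <- piv_pass(pr$a, pr$b, 64, 0.5)
  expect_equal(mean(f$u[f$valid]), 4, tolerance = 0.1)
  expect_equal(mean(f$v[f$valid]), 2, tolerance = 0.1)

  rp <- rotated_pair(0.01)
  fr <- piv_pass(rp$a, rp$b, 64, 0.5)
  truth <- rp$disp_at(rep(fr$x, each = length(fr$y)),
                      rep(fr$y, times = length(fr$x)))
  ok <- as.vector(fr$valid)
  rms <- sqrt(mean((as.vector(fr$u) - truth[, 1])[ok]^2 +
                   (as.vector(fr$v) - truth[, 2])[ok]^2))
  expect_lt(rms, 0.2)
  expect_error(piv_pass(pr$a, pr$b, 512, 0.5), "window larger")
})

test_that("two_pass_piv meets the translation and anti-symmetry contracts", {
  pr <- translated_pair(c(9.5, 0))
  f <- two_pass_piv(pr$a, pr$b, piv_params(), preprocess = FALSE)
  expect_equal(diff(f$x)[1], 16)   # pass-2 grid: 32 px at 50% overlap
  expect_equal(mean(f$u[f$valid]), 9.5, tolerance = 0.2)
  expect_equal(mean(f$v[f$valid]), 0, tolerance = 0.2)
  # frame-swap antisymmetry on interior nodes
  fr <- two_pass_piv(pr$b, pr$a, piv_params(), preprocess = FALSE)
  int <- 3:(length(f$y) - 2)
  expect_equal(mean(fr$u[int, int]), -mean(f$u[int, int]), tolerance = 0.1)
  # translation equivariance: shifting both frames identically changes
  # nothing at matching interior nodes
  sh <- function(m) m[, c(9:ncol(m), 1:8)]
  f2 <- two_pass_piv(sh(pr$a), sh(pr$b), piv_params(), preprocess = FALSE)
  expect_equal(f2$u[int, int], f$u[int, int], tolerance = 0.15)
})

test_that("two-pass beats one-pass under strong shear", {
  # displacement gradient 0.3 px/px across the image
  n <- 256L
  pos <- polonaise:::with_seed(11, cbind(runif(1500, 8, n - 8),
                                         runif(1500, 8, n - 8)))
  dx <- 0.3 * (pos[, 2] - n / 2)
  a <- render_spots(pos, c(n, n), sigma = 2)
  b <- render_spots(cbind(pos[, 1] + dx, pos[, 2]), c(n, n), sigma = 2)
  truth_u <- function(x, y) 0.3 * (y - n / 2)
  err_of <- function(f) {
    tu <- truth_u(rep(f$x, each = length(f$y)), rep(f$y, length(f$x)))
    int <- as.vector(f$valid)
    sqrt(mean((as.vector(f$u) - tu)[int]^2))
  }
  one <- validate_vectors(piv_pass(a, b, 64, 0.5), piv_params())
  two <- two_pass_piv(a, b, piv_params(), preprocess = FALSE)
  expect_lte(err_of(two), err_of(one))
})

test_that("sub-pixel sweep shows low peak-locking bias", {
  shifts <- seq(0.1, 0.9, by = 0.2)
  errs <- vapply(shifts, function(s) {
    pr <- translated_pair(c(s, 0), n_particles = 300, seed = 7)
    f <- two_pass_piv(pr$a, pr$b, piv_params(), preprocess = FALSE)
    abs(mean(f$u[f$valid]) - s)
  }, numeric(1))
  expect_lt(mean(errs), 0.15)
})

test_that("validate_vectors flags spikes and interpolates from neighbors", {
  u <- matrix(1, 5, 5); v <- matrix(0.5, 5, 5)
  u[3, 3] <- 10   # spike 10x the neighborhood median
  f <- velocity_field(1:5, 1:5, u, v)
  out <- validate_vectors(f, piv_params(smoothing = FALSE,
                                        max_displacement = Inf))
  expect_true(out$interpolated[3, 3])
  # oracle: iterative neighbor averaging of a constant field returns the
  # constant -> mean of the 4 valid neighbors
  expect_equal(out$u[3, 3], mean(c(u[2, 3], u[4, 3], u[3, 2], u[3, 4])),
               tolerance = 1e-5)
  expect_equal(out$v[3, 3], 0.5, tolerance = 1e-5)
  # outlier-free smooth field passes through unchanged
  g <- velocity_field(1:5, 1:5, matrix(seq(0, 1, length.out = 25), 5),
                      matrix(0, 5, 5))
  out2 <- validate_vectors(g, piv_params(smoothing = FALSE,
                                         max_displacement = Inf))
  expect_equal(out2$u, g$u)
  expect_false(any(out2$interpolated))
  # all-zero field: no outliers
  z <- velocity_field(1:5, 1:5, matrix(0, 5, 5), matrix(0, 5, 5))
  out3 <- validate_vectors(z, piv_params(smoothing = FALSE))
  expect_equal(out3$u, z$u)
  expect_error(validate_vectors(velocity_field(1:2, 1:2, matrix(0, 2, 2),
                                               matrix(0, 2, 2))),
               "3x3")
})

test_that("calibrate converts units once and exactly", {
  u <- matrix(2, 4, 4); v <- matrix(-1, 4, 4)
  f <- velocity_field((1:4) * 16, (1:4) * 16, u, v, units = "px_per_frame")
  cal <- calibrate(f, pixel_size = 3.25, frame_interval = 180)
  expect_equal(cal$u[1, 1], 2 * 3.25 / 180)   # 0.036111... um/s
  expect_equal(cal$units, "um_per_s")
  expect_equal(cal$x, f$x * 3.25)
  expect_error(calibrate(cal, 3.25, 180), "already calibrated")
  # round-trip with inverse factors
  back <- velocity_field(cal$x / 3.25, cal$y / 3.25, cal$u * 180 / 3.25,
                         cal$v * 180 / 3.25, units = "px_per_frame")
  expect_equal(back$u, f$u, tolerance = 1e-12)
  # zero field stays zero, units change
  z <- velocity_field(1:4, 1:4, matrix(0, 4, 4), matrix(0, 4, 4),
                      units = "px_per_frame")
  expect_equal(max(abs(calibrate(z, 2, 10)$u)), 0)
})

test_that("piv parameter validation rejects malformed settings", {
  expect_error(piv_params(pass1_window = 48), "powers of two")
  expect_error(piv_params(pass2_window = 128), "pass2_window")
  expect_error(piv_params(overlap_fraction = 1), "overlap_fraction")
})
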