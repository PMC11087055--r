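# Flow-model construction, analytic velocities, advection, rendering.

test_that("condition presets build the documented flow geometries", {
  m <- build_flow_model("control")
  sep <- sqrt(sum((m$primary_pair[[1]]$center - m$primary_pair[[2]]$center)^2))
  expect_equal(sep, 860.2, tolerance = 1e-12)
  expect_null(m$secondary_pair)
  expect_equal(m$envelopes$primary$kind, "ramp")
  expect_equal(m$duration, 36000)
  # opposite circulation, mirrored across the midline (x = 0)
  expect_equal(m$primary_pair[[1]]$circulation_sign *
               m$primary_pair[[2]]$circulation_sign, -1)
  expect_equal(m$primary_pair[[1]]$center[1],
               -m$primary_pair[[2]]$center[1])

  d <- build_flow_model("ddep")
  expect_equal(sqrt(sum((d$primary_pair[[1]]$center -
                         d$primary_pair[[2]]$center)^2)), 1008.4)

  a <- build_flow_model("aphidicolin")
  expect_equal(a$envelopes$primary$kind, "ramp_then_decay")
  expect_equal(a$envelopes$primary$t_decay, 2.2 * 3600)

  v <- build_flow_model("vg1")
  expect_false(is.null(v$secondary_pair))
  expect_equal(v$envelopes$secondary$t_on, 3600)
  # secondary pair is the primary rotated pi about the disc center
  expect_equal(v$secondary_pair[[1]]$center,
               -v$primary_pair[[1]]$center)

  expect_error(build_flow_model("nonsense"), "valid presets")
  expect_error(build_flow_model("control",
                                list(pair_separation = 4000)),
               "disc diameter")
  expect_error(build_flow_model("control", list(bogus_field = 1)),
               "unknown override")
})

test_that("amplitude envelopes stay in [0, 1] and decay as declared", {
  t <- seq(0, 36000, by = 60)
  for (env in list(amplitude_envelope("constant"),
                   amplitude_envelope("ramp", t_ramp = 3600),
                   amplitude_envelope("ramp_then_decay", t_ramp = 3600,
                                      t_decay = 7920),
                   amplitude_envelope("crossfade", t_ramp = 1800,
                                      t_on = 3600))) {
    v <- envelope_value(env, t)
    expect_true(all(v >= 0 & v <= 1))
  }
  dec <- amplitude_envelope("ramp_then_decay", t_ramp = 3600, t_decay = 7920)
  after <- envelope_value(dec, seq(7920, 36000, by = 60))
  expect_true(all(diff(after) <= 1e-12))      # non-increasing after t_decay
  expect_equal(envelope_value(dec, 7920), 0)  # flow has ceased at t_decay
  expect_equal(envelope_value(dec, 5000), 1)  # plateau before decay window
})

test_that("velocity_at respects boundary, core, and symmetry properties", {
  m <- build_flow_model("control")
  # exactly zero at and outside the disc edge
  expect_equal(velocity_at(m, c(1500, 0), 7200), matrix(0, 1, 2))
  expect_equal(velocity_at(m, c(1800, 900), 7200), matrix(0, 1, 2))
  # vanishing azimuthal profile at a vortex center
  single <- flow_model(
    primary_pair = list(vortex_spec(c(-300, 0), +1, 0.2, 250),
                        vortex_spec(c(1300, 0), -1, 0, 250)),
    envelopes = list(primary = amplitude_envelope("constant")))
  ctr <- velocity_at(single, c(-300, 0), 0)
  expect_equal(max(abs(ctr)), 0, tolerance = 1e-12)
  # rotational antisymmetry about a single core
  p1 <- c(-300 + 120, 0); p2 <- c(-300 - 120, 0)
  v12 <- velocity_at(single, rbind(p1, p2), 0)
  expect_equal(v12[1, ], -v12[2, ], tolerance = 1e-9)
  expect_error(velocity_at(m, c(NA, 0), 0), "non-finite")
})

test_that("the envelope modulates speeds bounded by the summed core peaks", {
  m <- build_flow_model("control")
  pts <- polonaise:::with_seed(8, cbind(runif(4000, -1500, 1500),
                                        runif(4000, -1500, 1500)))
  # between the cores the two azimuthal tails add constructively, so the
  # sharp bound is the sum of the core peak speeds, times the envelope
  peak_sum <- sum(vapply(m$primary_pair, function(v) v$peak_speed,
                         numeric(1)))
  spd_full <- sqrt(rowSums(velocity_at(m, pts, 36000)^2))  # envelope = 1
  expect_lte(max(spd_full), peak_sum * (1 + 1e-9))
  for (t in c(0, 1200, 2400)) {
    spd <- sqrt(rowSums(velocity_at(m, pts, t)^2))
    e <- envelope_value(m$envelopes$primary, t)
    expect_lte(max(spd), peak_sum * e + 1e-12)
    expect_equal(spd, e * spd_full, tolerance = 1e-9)
  }
})

test_that("model fields are divergence-free with mirror-antisymmetric vorticity", {
  m <- build_flow_model("control", list(t_ramp = 1))  # envelope ~1 at t>0
  f <- model_field(m, t = 3600, gx = seq(-1250, 1250, by = 25))
  vm <- vorticity(f)
  dv <- divergence(f)
  # the azimuthal superposition is divergence-free in the disc interior;
  # inside the taper ring (r > 1350) the radial taper deliberately trades
  # exact incompressibility for a smooth edge, so the check stops short
  rr <- sqrt(outer(rep(1, length(f$y)), f$x)^2 +
             outer(f$y, rep(1, length(f$x)))^2)
  inn <- rr <= 1300
  expect_lt(max(abs(dv$values[dv$valid & inn])),
            0.01 * max(abs(vm$values[vm$valid & inn])))
  # mirroring across the midline (x -> -x) negates vorticity point-wise
  nx <- length(f$x)
  mirr <- velocity_field(f$x, f$y, -f$u[, nx:1], f$v[, nx:1],
                         units = "um_per_s")
  vm2 <- vorticity(mirr)
  expect_equal(vm2$values, -vm$values[, nx:1], tolerance = 1e-9)
})

test_that("advection conserves particles, is deterministic, and matches a fine-step oracle", {
  single <- flow_model(
    primary_pair = list(vortex_spec(c(0, 0), +1, 0.2, 250),
                        vortex_spec(c(1300, 0), -1, 0, 250)),
    envelopes = list(primary = amplitude_envelope("constant")),
    edge_taper_width = 150)
  times <- seq(0, 3600 * 3, by = 180)
  r0 <- 400
  ens <- advect_particles(single, c(r0, 0), times)
  expect_equal(dim(ens$positions), c(1L, 2L, length(times)))
  # circular orbit: radius conserved within 1%
  rr <- sqrt(ens$positions[1, 1, ]^2 + ens$positions[1, 2, ]^2)
  expect_true(all(abs(rr - r0) <= 0.01 * r0))
  # agreement with a 100x finer-step integration
  oracle <- oracle_advect(single, c(r0, 0), times, refine = 100L)
  err <- sqrt(rowSums((t(ens$positions[1, , ]) - oracle)^2))
  expect_lt(max(err), 0.01 * r0)
})

test_that("mirrored particle pairs follow mirror-image trajectories", {
  m <- build_flow_model("control")
  times <- seq(0, 7200, by = 180)
  ens <- advect_particles(m, rbind(c(-500, 200), c(500, 200)), times)
  left <- t(ens$positions[1, , ])
  right <- t(ens$positions[2, , ])
  expect_equal(left[, 1], -right[, 1], tolerance = 1e-6)
  expect_equal(left[, 2], right[, 2], tolerance = 1e-6)
})

test_that("zero-amplitude flow leaves particles in place", {
  m <- build_flow_model("control", list(peak_speed = 0))
  times <- seq(0, 3600, by = 180)
  ens <- advect_particles(m, rbind(c(100, 50), c(-600, 400)), times)
  expect_equal(ens$positions[, , length(times)], ens$positions[, , 1])
})

test_that("rendering is deterministic, centered, and omits out-of-frame spots", {
  params <- imaging_params(frame_count = 3, image_shape = c(128L, 128L),
                           pixel_size = 4, noise_model = "gaussian")
  m <- build_flow_model("control", list(disc_radius = 200,
                                        pair_separation = 150,
                                        core_radius = 60,
                                        edge_taper_width = 40))
  times <- params$frame_interval * (0:2)
  ens <- advect_particles(m, rbind(c(0, 0), c(100, -80)), times)
  s1 <- render_frames(ens, params, seed = 9)
  s2 <- render_frames(ens, params, seed = 9)
  expect_identical(s1$frames, s2$frames)          # same seed, same movie
  s3 <- render_frames(ens, params, seed = 10)
  expect_false(identical(s1$frames, s3$frames))
  # noise-free single static particle: argmax at its pixel
  quiet <- imaging_params(frame_count = 2, image_shape = c(64L, 64L),
                          pixel_size = 1, noise_model = "none",
                          background_level = 0)
  still <- advect_particles(build_flow_model("control",
                                             list(peak_speed = 0,
                                                  disc_radius = 30,
                                                  pair_separation = 20,
                                                  core_radius = 10,
                                                  edge_taper_width = 5)),
                            matrix(c(10, -7), 1), quiet$frame_interval * (0:1))
  st <- render_frames(still, quiet, seed = 1)
  pk <- which(st$frames[[1]] == max(st$frames[[1]]), arr.ind = TRUE)
  # physical (10, -7) um -> col 32.5 + 10, row 32.5 + 7
  expect_equal(unname(pk[1, ]), c(40, 43), tolerance = 1)
  # spot outside the frame is silently dropped
  img <- render_spots(cbind(500, 500), c(64, 64), sigma = 2)
  expect_equal(sum(img), 0)
})

test_that("generate_condition seeds the disc uniformly and reproducibly", {
  imaging <- imaging_params(frame_count = 3, image_shape = c(128L, 128L),
                            pixel_size = 26)
  g1 <- generate_condition("control", imaging, n_particles = 500, seed = 4)
  g2 <- generate_condition("control", imaging, n_particles = 500, seed = 4)
  expect_identical(g1$ensemble$positions, g2$ensemble$positions)
  expect_identical(g1$stack$frames, g2$stack$frames)
  r <- sqrt(rowSums(g1$ensemble$positions[, , 1]^2))
  expect_true(all(r <= g1$model$disc_radius))
  expect_equal(length(g1$ensemble$ids), 500L)
})

test_that("aphidicolin ground-truth displacements decay after t_decay", {
  imaging <- imaging_params(frame_count = 60, image_shape = c(64L, 64L),
                            pixel_size = 52)
  g <- generate_condition("aphidicolin", imaging, n_particles = 300, seed = 2)
  pos <- g$ensemble$positions
  step <- sapply(seq_len(dim(pos)[3] - 1), function(k) {
    mean(sqrt(rowSums((pos[, , k + 1] - pos[, , k])^2)))
  })
  t_mid <- g$ensemble$times[-1] / 3600
  expect_gt(mean(step[t_mid > 1 & t_mid < 1.6]), 10 * mean(step[t_mid > 2.4]))
  expect_lt(mean(step[t_mid > 2.4]), 1e-6)
})

test_that("trajectory and image-stack round-trips preserve the data", {
  imaging <- imaging_params(frame_count = 3, image_shape = c(64L, 64L),
                            pixel_size = 52)
  g <- generate_condition("control", imaging, n_particles = 20, seed = 1)
  tf <- tempfile(fileext = ".csv")
  write_trajectories(g$ensemble, tf)
  df <- read.csv(tf)
  expect_equal(nrow(df), 20 * 3)
  expect_equal(df$x_um[df$t_s == 0], g$ensemble$positions[, 1, 1])
  tif <- tempfile(fileext = ".tif")
  write_image_stack(g$stack, tif)
  rt <- read_image_stack(tif, pixel_size = 52, frame_interval = 180)
  expect_equal(length(rt$frames), 3L)
  # 16-bit quantization: intensities preserved to 1 count
  expect_lt(max(abs(rt$frames[[1]] - g$stack$frames[[1]])), 1.01)
  unlink(c(tf, tif))
})
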