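# Vortex-core detection, pattern scoring, separation, duration, and the
# group statistics.

# Grid corners stay inside r = 1350 um: the cosine edge taper generates a
# compensating vorticity ring at the disc margin (as any bounded vortex
# must), which core detection is not meant to pick up.
make_pair_field <- function(sep = 860.2, peak = 0.2, rc = 300,
                            gx = seq(-940, 940, by = 40)) {
  m <- build_flow_model("control", list(pair_separation = sep,
                                        peak_speed = peak,
                                        core_radius = rc, t_ramp = 1))
  model_field(m, t = 3600, gx = gx)
}

test_that("detect_cores finds mirrored cores and ignores translation", {
  f <- make_pair_field()
  cores <- detect_cores(vorticity(f), min_separation = 200)
  expect_length(cores, 2L)
  expect_equal(sort(vapply(cores, function(cr) cr$sign, numeric(1))),
               c(-1, 1))
  pos <- t(vapply(cores, function(cr) cr$position, numeric(2)))
  # each core within one grid spacing of its generator position
  expect_lt(min(abs(pos[, 1] - 430.1)), 40)
  expect_lt(min(abs(pos[, 1] + 430.1)), 40)
  expect_lt(max(abs(pos[, 2])), 40)
  expect_true(all(vapply(cores, function(cr) cr$support_radius, numeric(1)) > 0))
  # uniform translation has no cores
  expect_length(detect_cores(vorticity(uniform_field(0.1, 0.05)),
                             min_abs_vorticity = 1e-6), 0L)
  bad <- vorticity(uniform_field(1, 1))
  bad$valid[] <- FALSE
  expect_error(detect_cores(bad), "no valid nodes")
})

test_that("a single synthetic vortex is localized within one grid spacing", {
  m <- flow_model(primary_pair = list(vortex_spec(c(260, -180), +1, 0.2, 250),
                                      vortex_spec(c(-1300, 0), -1, 1e-6,
                                                  250)),
                  envelopes = list(primary = amplitude_envelope("constant")))
  f <- model_field(m, 0, gx = seq(-900, 900, by = 40))
  cores <- detect_cores(vorticity(f), min_separation = 200)
  expect_gte(length(cores), 1L)
  expect_lt(sqrt(sum((cores[[1]]$position - c(260, -180))^2)), 40)
  expect_equal(cores[[1]]$sign, 1)
})

test_that("detect_polonaise accepts bilateral pairs and explains failures", {
  pat <- detect_polonaise(make_pair_field())
  expect_true(pat$detected)
  expect_equal(pat$left_core$sign * pat$right_core$sign, -1)
  expect_gt(pat$left_core$position[1] * pat$right_core$position[1], -Inf)
  expect_equal(pat$separation, 860.2, tolerance = 0.05 * 860.2)
  # translation field: no cores
  none <- detect_polonaise(uniform_field(0.1, 0))
  expect_false(none$detected)
  expect_match(none$reasons, "no cores")
  # two same-signed vortices on one side: no qualifying pair
  m2 <- flow_model(primary_pair = list(vortex_spec(c(400, 300), +1, 0.2, 200),
                                       vortex_spec(c(400, -300), -1, 1e-6,
                                                   200)),
                   secondary_pair = list(vortex_spec(c(800, 300), +1, 0.2,
                                                     200),
                                         vortex_spec(c(800, -300), -1, 1e-6,
                                                     200)),
                   envelopes = list(primary = amplitude_envelope("constant"),
                                    secondary = amplitude_envelope("constant")))
  f2 <- model_field(m2, 0, gx = seq(-1200, 1200, by = 40))
  same <- detect_polonaise(f2, midline_angle = pi / 2,
                           params = polonaise_params(min_abs_vorticity = 2e-4,
                                                     max_core_radius = 1300))
  expect_false(same$detected)
  expect_match(same$reasons, "bilateral")
})

test_that("separation measures core distance and errors when undetected", {
  pat <- detect_polonaise(make_pair_field())
  pat$left_core$position <- c(-430.1, 0)
  pat$right_core$position <- c(430.1, 0)
  expect_equal(measure_separation(pat), 860.2)
  none <- detect_polonaise(uniform_field(1, 0))
  expect_error(measure_separation(none), "detected")
})

test_that("separation is invariant under rigid motion and velocity scaling", {
  f <- make_pair_field()
  base <- detect_polonaise(f)
  # scale all velocities by 3: same cores, tripled peak vorticity
  f3 <- velocity_field(f$x, f$y, 3 * f$u, 3 * f$v, units = "um_per_s")
  p3 <- detect_polonaise(f3)
  expect_equal(p3$separation, base$separation, tolerance = 1e-9)
  expect_equal(p3$left_core$peak_vorticity, 3 * base$left_core$peak_vorticity,
               tolerance = 1e-9)
  # rotate the whole configuration (cores and midline) by 90 degrees
  m_rot <- flow_model(
    midline_axis_angle = 0,
    primary_pair = list(vortex_spec(c(0, 430.1), +1, 0.2, 300),
                        vortex_spec(c(0, -430.1), -1, 0.2, 300)),
    envelopes = list(primary = amplitude_envelope("constant")))
  f_rot <- model_field(m_rot, 0)
  p_rot <- detect_polonaise(f_rot, midline_angle = 0)
  expect_true(p_rot$detected)
  expect_equal(p_rot$separation, base$separation, tolerance = 40)
})

test_that("polonaise_duration scores persistent, decaying, and null series", {
  gx <- seq(-1200, 1200, by = 60)
  mk_series <- function(env_fun) {
    m <- build_flow_model("control", list(t_ramp = 1))
    fields <- lapply(seq(0, 10800, by = 540), function(t) {
      f <- model_field(m, 3600, gx = gx)  # full-strength template
      a <- env_fun(t)
      velocity_field(f$x, f$y, a * f$u, a * f$v, units = "um_per_s", t = t)
    })
    field_series(fields)
  }
  persistent <- polonaise_duration(mk_series(function(t) 1))
  expect_equal(persistent$t0, 0)
  # fields on a 540 s grid: the last 30-min window starts at 8640 s, so a
  # fully detected 3 h series scores (8640 + 1800) / 3600 = 2.9 h
  expect_equal(persistent$duration_h, 2.9, tolerance = 1e-9)
  expect_true(all(persistent$detected))

  # amplitude dies at 1.5 h: duration close to that
  dec <- polonaise_duration(mk_series(function(t) as.numeric(t < 5400)))
  expect_lt(dec$duration_h, 2.1)
  expect_gt(dec$duration_h, 1.4)

  null <- polonaise_duration(mk_series(function(t) 0))
  expect_equal(null$duration_h, 0)
  expect_true(null$never_detected)

  # appending detected windows never shortens the run
  longer <- mk_series(function(t) 1)
  shorter <- field_series(longer$fields[1:10])
  expect_gte(polonaise_duration(longer)$duration_h,
             polonaise_duration(shorter)$duration_h)
})

test_that("compare_groups matches closed-form t and ANOVA conventions", {
  # hand computation: n = 4 each, means 6.5 and 2.2, both SD 1.2 ->
  # t = (6.5 - 2.2) / (1.2 * sqrt(2/4)) = 5.0676..., df = 6,
  # p = 2 * P(T6 < -5.0676) = 0.002293
  g <- function(mu, s) { x <- c(-1.5, -0.5, 0.5, 1.5); mu + x / sd(x) * s }
  cmp <- compare_groups(list(control = g(6.5, 1.2), treated = g(2.2, 1.2)))
  expect_equal(cmp$statistic, 5.068, tolerance = 5e-4)
  expect_equal(cmp$df, 6)
  expect_equal(cmp$p, 0.002293, tolerance = 1e-3)
  # identical groups: t = 0, p = 1
  same <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # three equal groups: F = 0, p = 1
  an <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)),
                       test = "oneway_anova")
  expect_equal(an$statistic, 0)
  expect_equal(an$p, 1)
  # Welch reduces to close-to-pooled under equal variances
  w <- compare_groups(list(a = g(6.5, 1.2), b = g(2.2, 1.2)),
                      test = "welch_t")
  expect_equal(w$statistic, cmp$statistic, tolerance = 1e-9)
  # degenerate constants
  const_eq <- compare_groups(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(const_eq$p, 1)
  const_ne <- compare_groups(list(a = c(2, 2), b = c(3, 3)))
  expect_equal(const_ne$p, 0)
  expect_error(compare_groups(list(a = 1, b = c(1, 2))), "n >= 2")
  expect_error(compare_groups(list(a = c(1, 2))), "at least two")
  expect_error(compare_groups(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)),
                              test = "student_t"), "exactly two")
})
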