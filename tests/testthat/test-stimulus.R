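test_that("scale constant matches the mean-cosine Monte-Carlo oracle", {
  expect_identical(scale_constant(0), 1)
  set.seed(101)
  for (p in c(0.25, 0.5, 0.8)) {
    cosines <- cos(runif(4e6, -pi * p, pi * p))
    m <- mean(cosines)
    oracle <- 1 / m
    # delta-method standard error of the reciprocal mean
    se_c <- stats::sd(cosines) / sqrt(length(cosines)) / m^2
    expect_lt(abs(scale_constant(p) - oracle), 3 * se_c)
  }
  expect_equal(scale_constant(0.5), pi / 2, tolerance = 1e-12)
  expect_gt(scale_constant(0.998), 100)  # divergence toward 100% noise
  expect_error(scale_constant(1), "diverges")
})

test_that("visual angles reproduce the annulus geometry", {
  expect_equal(round(visual_angle(0.48, 0.60)), 44)
  expect_equal(round(visual_angle(2.44, 0.60)), 128)
  expect_equal(visual_angle(0, 1), 0)
  expect_error(visual_angle(1, 0), "> 0")
  expect_error(visual_angle(-1, 1), ">= 0")
})

test_that("dot count follows density times annulus area", {
  expect_equal(n_dots(annulus_spec()), 6563)
  expect_equal(n_dots(annulus_spec(dot_density = 0)), 0)
  expect_equal(n_dots(annulus_spec(inner_diameter = 2.44)), 0)
})

test_that("zero noise advances every dot rigidly by omega * dt", {
  set.seed(7)
  ann <- annulus_spec()
  field <- make_dot_field(ann, n = 500)
  nz <- noise_spec(0, field_velocity = 16, frame_rate = 60)
  adv <- advance_frame(field, nz)
  daz <- attr(adv, "daz")
  keep <- !is.na(daz)
  expect_true(all(abs(daz[keep] - 16 / 60 * pi / 180) < 1e-12))
})

test_that("noisy jumps are velocity-preserving in expectation", {
  set.seed(8)
  mv <- measure_field_velocity(noise_spec(0.8, 16, 60), n_frames = 40,
                               n_dots = 500)
  expect_gte(mv$n, 1e4)
  expect_lt(abs(mv$mean_deg_s - 16), 3 * mv$se_deg_s)
})

test_that("single-frame jump magnitude grows by the scale constant", {
  set.seed(9)
  ann <- annulus_spec()
  field <- make_dot_field(ann, n = 200)
  nz <- noise_spec(0.8, 16, 60)
  x0 <- field$r * cos(field$az); y0 <- field$r * sin(field$az)
  adv <- advance_frame(field, nz)
  keep <- !attr(adv, "respawned")
  jump <- sqrt((adv$r[keep] * cos(adv$az[keep]) - x0[keep])^2 +
                 (adv$r[keep] * sin(adv$az[keep]) - y0[keep])^2)
  rigid <- 2 * field$r[keep] * sin(16 * pi / 180 / 60 / 2)  # rotation chord
  expect_equal(jump / rigid, rep(scale_constant(0.8), sum(keep)),
               tolerance = 1e-10)
  expect_equal(scale_constant(0.8), 4.276, tolerance = 1e-3)
})

test_that("dots never leave the annulus", {
  set.seed(10)
  ann <- annulus_spec()
  field <- make_dot_field(ann, n = 300)
  nz <- noise_spec(0.8, 16, 60)
  for (f in 1:30) {
    field <- advance_frame(field, nz)
    expect_true(all(field$r >= ann$inner_diameter / 2 - 1e-12))
    expect_true(all(field$r <= ann$outer_diameter / 2 + 1e-12))
  }
})

test_that("unscaled full noise yields zero net motion", {
  set.seed(11)
  nz <- structure(list(noise_fraction = 1, field_velocity = 16,
                       frame_rate = 60), class = "svv_noise")
  mv <- measure_field_velocity(nz, n_frames = 60, n_dots = 500,
                               rescale = FALSE)
  expect_lt(abs(mv$mean_deg_s), 3 * mv$se_deg_s)
})

test_that("noise spec enforces the tested range", {
  expect_error(noise_spec(0.9), "0.8")
  expect_error(noise_spec(-0.1), "0.8")
  expect_silent(noise_spec(0.8))
})

test_that("bar noise meets its calibration: SD, range, bandwidth", {
  set.seed(12)
  traces <- replicate(300, generate_bar_noise())
  expect_equal(stats::sd(as.vector(traces)), 9.6, tolerance = 0.02)
  expect_true(all(abs(traces) <= 35.9))
  expect_lt(abs(mean(traces)), 0.5)
  # spectral purity: negligible power above 0.25 Hz
  pg <- apply(traces[, 1:20], 2, function(x) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = 30), taper = 0,
                            detrend = FALSE, plot = FALSE)
    sum(sp$spec[sp$freq > 0.25]) / sum(sp$spec)
  })
  expect_true(all(pg < 0.01))
})

test_that("bar noise is reproducible bit-for-bit under a fixed seed", {
  set.seed(42)
  a <- generate_bar_noise()
  set.seed(42)
  b <- generate_bar_noise()
  expect_identical(a, b)
  expect_error(generate_bar_noise(duration_s = 0), "> 0")
})

test_that("dot field positions export is tidy", {
  set.seed(13)
  field <- make_dot_field(annulus_spec(), n = 10)
  tb <- dot_field_positions(field, frame = 3L)
  expect_named(tb, c("frame", "dot_id", "x_m", "y_m"))
  expect_equal(nrow(tb), 10)
  expect_equal(sqrt(tb$x_m^2 + tb$y_m^2), field$r)
})
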