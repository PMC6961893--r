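test_that("schedule counts match the design", {
  set.seed(21)
  sch <- build_schedule()
  expect_equal(nrow(sch), 264)
  expect_equal(as.integer(table(sch$session)), rep(66L, 4))
  counts <- dplyr::count(sch, velocity, noise, direction)
  expect_true(all(counts$n == 4))
  expect_equal(nrow(counts), 66)  # 33 conditions x 2 directions
  for (cell in list(c(16, 0.8), c(16, 0.7), c(8, 0.8))) {
    expect_equal(sum(sch$velocity == cell[1] & sch$noise == cell[2]), 0)
  }
})

test_that("feasible design has 33 cells", {
  expect_equal(nrow(feasible_conditions()), 33)
  expect_equal(nrow(reference_window_means()), 33)
})

test_that("an unresponsive, noise-free subject produces a flat trace", {
  set.seed(22)
  plat <- plateau_preset("table1")
  plat$plateau_deg <- 0
  prof <- subject_profile(plat, tracking_sd = 0)
  tr <- generate_trial(prof, 16, 0, "ccw")
  expect_true(all(abs(tr$bar_angle[tr$time > 5]) < 1e-6))
})

test_that("noise-free trials hit the calibrated window mean", {
  set.seed(23)
  prof <- noiseless_profile()
  tr <- generate_trial(prof, 16, 0, "ccw")
  expect_equal(nrow(tr), 1500)
  expect_equal(window_mean(tr$bar_angle, tr$time), 7.0, tolerance = 1e-3)
  tr2 <- generate_trial(prof, 4, 0.5, "ccw")
  expect_equal(window_mean(tr2$bar_angle, tr2$time), 2.8, tolerance = 1e-3)
})

test_that("same-seed CW and CCW trials are mirror images", {
  prof <- subject_profile(tracking_sd = 2, intercept = 0)
  set.seed(24)
  a <- generate_trial(prof, 8, 0.25, "ccw")
  set.seed(24)
  b <- generate_trial(prof, 8, 0.25, "cw")
  expect_equal(a$bar_angle, -b$bar_angle, tolerance = 1e-12)
})

test_that("the model plateau preset reflects attenuated simulations", {
  plat <- plateau_preset("model")
  expect_equal(nrow(plat), 33)
  p16 <- plat$target_window_mean_deg[plat$velocity == 16 & plat$noise == 0]
  expect_equal(p16, 7.46, tolerance = 0.01)
  # attenuation ordering carries into the preset
  v16 <- plat[plat$velocity == 16, ]
  expect_true(all(diff(v16$plateau_deg[order(v16$noise)]) < 0))
})

test_that("reduction recovers the generator exactly on noise-free cohorts", {
  set.seed(25)
  coh <- noiseless_cohort(n_subjects = 2)
  summ <- fold_average(coh)
  target <- reference_window_means()
  joined <- dplyr::inner_join(summ$meta, target,
                              by = c("velocity", "noise"))
  expect_equal(nrow(joined), 66)  # 33 conditions x 2 subjects
  expect_true(all(abs(joined$window_mean_deg - joined$mean_deg) < 1e-3))
})

test_that("2AFC generator yields the full factorial trial table", {
  set.seed(26)
  afc <- generate_2afc_dataset(n_subjects = 2)
  expect_equal(nrow(afc), 2 * 448)
  cells <- dplyr::count(afc, subject, velocity, noise)
  expect_true(all(cells$n == 16))
  expect_true(all(afc$response %in% c("faster", "slower")))
})

test_that("generating PSE drops by slope times noise", {
  set.seed(27)
  afc <- generate_2afc_dataset(n_subjects = 50, pse_slope = -1.6,
                               slope_sd = 0)
  gp <- attr(afc, "generating_pse")
  d <- mean(gp$pse[gp$noise == 0.6]) - mean(gp$pse[gp$noise == 0])
  expect_equal(d, -0.96, tolerance = 1e-12)
})

test_that("responses at the PSE are at chance when lapse is zero", {
  set.seed(28)
  afc <- generate_2afc_dataset(n_subjects = 60, pse_slope = 0,
                               slope_sd = 0, lapse = 0)
  at_pse <- afc[afc$velocity == 6 & afc$noise == 0, ]
  prop <- mean(at_pse$response == "faster")
  se <- sqrt(0.25 / nrow(at_pse))
  expect_lt(abs(prop - 0.5), 3 * se)
})

test_that("direction folding is unbiased between CW and CCW", {
  set.seed(29)
  coh <- generate_cohort(n_subjects = 4)
  dt <- direction_test(coh)
  expect_equal(nrow(dt), 33)
  expect_equal(dt$threshold[1], 0.05 / 33)
  expect_equal(sum(dt$significant), 0)
})

test_that("tidy export has one row per sample", {
  set.seed(30)
  grid <- design_grid(velocities = c(16), noise_levels = c(0),
                      omitted = cbind(velocity = numeric(0),
                                      noise = numeric(0)))
  coh <- generate_cohort(n_subjects = 1, grid = grid)
  tb <- trials_as_tibble(coh)
  expect_equal(nrow(tb), nrow(coh$angle) * 1500)
  expect_named(tb, c("subject", "session", "trial", "velocity", "noise",
                     "direction", "time", "bar_angle"))
})
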