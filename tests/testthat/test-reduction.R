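make_time <- function() (0:1499) / 30

test_that("rebasing zeros the 5-10 s baseline and ignores offsets", {
  tm <- make_time()
  expect_true(all(rebase_trace(rep(12, 1500), tm) == 0))
  set.seed(31)
  x <- rnorm(1500)
  expect_equal(rebase_trace(x + 57.3, tm), rebase_trace(x, tm),
               tolerance = 1e-10)
  idx <- tm >= 5 & tm <= 10
  expect_equal(mean(rebase_trace(x, tm)[idx]), 0, tolerance = 1e-12)
  expect_error(rebase_trace(x[1:30], tm[1:30] / 100), "baseline")
})

test_that("window mean matches the analytic exponential integral", {
  tm <- make_time()
  expect_equal(window_mean(rep(5, 1500), tm), 5)
  expect_equal(window_mean(rep(0, 1500), tm), 0)
  a <- 7.0; tau <- 11.4; onset <- 10
  y <- ifelse(tm >= onset, a * (1 - exp(-(tm - onset) / tau)), 0)
  # independent closed form: mean of a(1-e^(-x/tau)) over x in [17, 30]
  oracle <- a * (1 - tau / 13 * (exp(-17 / tau) - exp(-30 / tau)))
  expect_equal(window_mean(y, tm), oracle, tolerance = 1e-3)
  expect_error(window_mean(y[1:300], tm[1:300]), "window")
})

test_that("rebase plus window mean is invariant to constant offsets", {
  tm <- make_time()
  set.seed(32)
  x <- cumsum(rnorm(1500, sd = 0.05))
  for (off in c(-20, 3, 100)) {
    expect_equal(window_mean(rebase_trace(x + off, tm), tm),
                 window_mean(rebase_trace(x, tm), tm), tolerance = 1e-10)
  }
})

# builds an svv_trials object from a list of (subject, velocity, noise,
# direction, trace) rows
manual_trials <- function(rows, tm = make_time()) {
  meta <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(subject = r$subject, session = 1L, trial = 1L,
                   velocity = r$velocity, noise = r$noise,
                   direction = r$direction)
  }))
  angle <- do.call(rbind, lapply(rows, `[[`, "trace"))
  structure(list(meta = meta, angle = angle, time = tm,
                 profiles = list()), class = "svv_trials")
}

test_that("folding inverts clockwise trials and averages pointwise", {
  tm <- make_time()
  base <- sin(tm / 5)
  trials <- manual_trials(list(
    list(subject = 1, velocity = 16, noise = 0, direction = "ccw",
         trace = base),
    list(subject = 1, velocity = 16, noise = 0, direction = "cw",
         trace = -base)))
  summ <- fold_average(trials)
  reb <- rebase_trace(base, tm)
  expect_equal(as.numeric(summ$trace[1, ]), reb, tolerance = 1e-12)
  expect_equal(summ$meta$n_trials, 2L)
})

test_that("folding a dataset labelled all-CCW is the identity average", {
  tm <- make_time()
  set.seed(33)
  traces <- lapply(1:4, function(i) rnorm(1500))
  trials <- manual_trials(lapply(traces, function(x) {
    list(subject = 1, velocity = 4, noise = 0.25, direction = "ccw",
         trace = x)
  }))
  summ <- fold_average(trials)
  manual <- Reduce(`+`, lapply(traces, rebase_trace, time = tm)) / 4
  expect_equal(as.numeric(summ$trace[1, ]), manual, tolerance = 1e-12)
})

test_that("averaging eight trials shrinks the variance about eightfold", {
  tm <- make_time()
  set.seed(34)
  rows <- lapply(1:8, function(i) {
    list(subject = 1, velocity = 8, noise = 0,
         direction = if (i <= 4) "cw" else "ccw",
         trace = rnorm(1500, sd = 2) * (if (i <= 4) -1 else 1))
  })
  summ <- fold_average(manual_trials(rows))
  ratio <- stats::var(as.numeric(summ$trace[1, ])) / 4
  expect_equal(ratio, 1 / 8, tolerance = 0.15)
})

test_that("omitted conditions are absent, not zero-filled", {
  set.seed(35)
  coh <- noiseless_cohort(n_subjects = 1)
  summ <- fold_average(coh)
  expect_equal(nrow(summ$meta), 33)
  expect_false(any(summ$meta$velocity == 16 & summ$meta$noise == 0.8))
})

test_that("identical CW and CCW magnitudes give t = 0, not significant", {
  tm <- make_time()
  base <- ifelse(tm >= 10, 3 * (1 - exp(-(tm - 10) / 11)), 0)
  rows <- list()
  for (s in 1:3) {
    scale <- c(1, 1.3, 0.7)[s]
    rows <- c(rows, list(
      list(subject = s, velocity = 16, noise = 0, direction = "ccw",
           trace = scale * base),
      list(subject = s, velocity = 16, noise = 0, direction = "cw",
           trace = -scale * base)))
  }
  dt <- direction_test(manual_trials(rows))
  expect_equal(dt$t, 0)
  expect_false(dt$significant)
})

test_that("exponential fit recovers noiseless parameters to six digits", {
  tm <- make_time()
  a <- 7.0; b <- 1 / 11.4; cc <- 0.3
  y <- ifelse(tm >= 10, a * (1 - exp(-b * (tm - 10))) + cc, 0)
  set.seed(36)
  fit <- fit_exponential(y, tm)
  expect_true(fit$converged)
  expect_equal(fit$a, a, tolerance = 1e-6)
  expect_equal(fit$b, b, tolerance = 1e-6)
  expect_equal(fit$c, cc, tolerance = 1e-5)
  expect_equal(fit$tau, 11.4, tolerance = 1e-6)
  # 63.2% identity of the functional form at x = 1/b
  expect_equal(fit$a * (1 - exp(-1)), 0.632 * fit$a, tolerance = 1e-3)
})

test_that("flat traces yield near-zero amplitude and no time constant", {
  tm <- make_time()
  set.seed(37)
  fit <- fit_exponential(rep(0, 1500), tm)
  expect_true(abs(fit$a) < 1e-6)
  expect_true(is.na(fit$tau))
})

test_that("grand-mean traces average subjects within condition", {
  set.seed(38)
  coh <- noiseless_cohort(n_subjects = 2)
  g <- grand_mean_traces(fold_average(coh))
  expect_equal(nrow(g$meta), 33)
  expect_true(all(g$meta$n_subjects == 2))
  gm <- g$meta$window_mean_deg[g$meta$velocity == 16 & g$meta$noise == 0]
  expect_equal(gm, 7.0, tolerance = 1e-3)
})
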