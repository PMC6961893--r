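#' Experimental design grid
#'
#' The factorial velocity x noise design with the three cells that were not
#' run (the largest dot jumps caused display duplication artifacts):
#' 16 deg/s at 70% and 80% noise, and 8 deg/s at 80% noise. 33 feasible
#' cells remain; each is run 4 times per rotation direction over 4 sessions.
#'
#' @param velocities Scene speeds (deg/s).
#' @param noise_levels Noise fractions.
#' @param omitted Two-column matrix (velocity, noise) of omitted cells.
#' @param reps_per_direction Trials per condition per direction.
#' @param sessions Number of sessions.
#' @return An object of class `svv_design`.
#' @export
design_grid <- function(velocities = c(1, 2, 4, 6, 8, 16),
                        noise_levels = c(0, 0.25, 0.5, 0.6, 0.7, 0.8),
                        omitted = cbind(velocity = c(16, 16, 8),
                                        noise = c(0.8, 0.7, 0.8)),
                        reps_per_direction = 4, sessions = 4) {
  structure(list(velocities = velocities, noise_levels = noise_levels,
                 omitted = omitted, reps_per_direction = reps_per_direction,
                 sessions = sessions, directions = c("cw", "ccw")),
            class = "svv_design")
}

#' Feasible conditions of a design
#'
#' @param grid [design_grid()].
#' @return Tibble with columns `velocity`, `noise` (omitted cells excluded).
#' @export
feasible_conditions <- function(grid = design_grid()) {
  cells <- expand.grid(velocity = grid$velocities, noise = grid$noise_levels,
                       KEEP.OUT.ATTRS = FALSE)
  om <- paste(grid$omitted[, 1], grid$omitted[, 2])
  keep <- !(paste(cells$velocity, cells$noise) %in% om)
  tibble::as_tibble(cells[keep, , drop = FALSE])
}

#' Build a randomized trial schedule
#'
#' Every feasible condition x direction pair appears exactly once per
#' session (66 trials/session); over the default 4 sessions each condition
#' accumulates 4 trials per direction (264 trials in total). Ordering within
#' each session is randomized with the current RNG state.
#'
#' @param grid [design_grid()].
#' @return Tibble with columns `session`, `trial`, `velocity`, `noise`,
#'   `direction`.
#' @export
build_schedule <- function(grid = design_grid()) {
  cond <- feasible_conditions(grid)
  base <- merge(cond, data.frame(direction = grid$directions))
  if (grid$reps_per_direction != grid$sessions) {
    base <- base[rep(seq_len(nrow(base)),
                     grid$reps_per_direction / grid$sessions), ]
  }
  out <- do.call(rbind, lapply(seq_len(grid$sessions), function(s) {
    block <- base[sample.int(nrow(base)), , drop = FALSE]
    data.frame(session = s, trial = seq_len(nrow(block)),
               velocity = block$velocity, noise = block$noise,
               direction = block$direction)
  }))
  tibble::as_tibble(out)
}

#' Condition-mean bar angles reported for the original cohort
#'
#' Grand-mean bar angle (degrees) over the 27-40 s analysis window for each
#' feasible velocity x noise condition, with across-subject standard
#' deviations, as published for the 10-participant cohort. These anchor the
#' `"table1"` synthetic-data preset.
#'
#' @return Tibble with columns `velocity`, `noise`, `mean_deg`, `sd_deg`.
#' @export
reference_window_means <- function() {
  v <- c(1, 2, 4, 6, 8, 16)
  tab <- rbind(
    # noise:  0.8   0.7   0.6   0.5   0.25  0
    c(0.4, 0.9, 1.2, 1.3, 1.3, 1.1),
    c(0.8, 1.3, 1.9, 2.0, 2.0, 1.6),
    c(0.9, 1.8, 2.2, 2.8, 2.8, 3.1),
    c(1.2, 2.2, 2.9, 2.8, 4.0, 3.9),
    c(NA, 2.3, 3.4, 3.7, 3.7, 4.7),
    c(NA, NA, 3.4, 5.0, 5.9, 7.0))
  sds <- rbind(
    c(1.1, 1.1, 0.8, 1.3, 1.2, 1.1),
    c(1.2, 2.0, 1.8, 1.2, 2.0, 2.5),
    c(1.6, 1.8, 2.1, 2.7, 2.9, 2.5),
    c(1.8, 2.3, 2.8, 3.0, 3.6, 4.0),
    c(NA, 3.0, 2.9, 3.1, 4.1, 3.7),
    c(NA, NA, 5.1, 4.7, 5.8, 6.9))
  noise <- c(0.8, 0.7, 0.6, 0.5, 0.25, 0)
  out <- expand.grid(velocity = v, noise = noise, KEEP.OUT.ATTRS = FALSE)
  out$mean_deg <- as.vector(tab)
  out$sd_deg <- as.vector(sds)
  tibble::as_tibble(out[!is.na(out$mean_deg), ])
}

# fraction of the plateau reached, on average, over the analysis window
# [w1, w2] s of trial time, for an exponential rise starting at motion onset
window_rise_fraction <- function(tau, onset = 10, window = c(27, 40)) {
  x1 <- window[1] - onset; x2 <- window[2] - onset
  1 - tau / (x2 - x1) * (exp(-x1 / tau) - exp(-x2 / tau))
}

#' Per-condition plateau amplitudes for a preset
#'
#' Amplitudes of the exponential bias rise used by the trial generator.
#' For `"table1"` they are calibrated so that a noise-free trial's 27-40 s
#' window mean equals the published condition grand mean (the window mean of
#' an exponential with a finite rise time falls short of its plateau, so the
#' amplitude is the tabled value divided by the window rise fraction). For
#' `"model"` the plateau is calibrated the same way to the mechanistic
#' model's predicted window mean at the published parameters.
#'
#' @param preset `"table1"` or `"model"`.
#' @param tau Rise time constant (s) assumed by the generator.
#' @param params Model parameters (used by the `"model"` preset).
#' @return Tibble with columns `velocity`, `noise`, `plateau_deg`,
#'   `target_window_mean_deg`.
#' @export
plateau_preset <- function(preset = c("table1", "model"), tau = 11.4,
                           params = model_params()) {
  preset <- match.arg(preset)
  frac <- window_rise_fraction(tau)
  if (preset == "table1") {
    tab <- reference_window_means()
    target <- tab$mean_deg
    out <- tab[, c("velocity", "noise")]
  } else {
    out <- feasible_conditions()
    target <- vapply(seq_len(nrow(out)), function(i) {
      pp <- apply_noise_attenuation(params, out$noise[i])
      sim <- svv_simulate(roll_protocol(out$velocity[i]), pp)
      mean(sim$bias[sim$time >= 27 & sim$time <= 40])
    }, numeric(1))
  }
  out$plateau_deg <- target / frac
  out$target_window_mean_deg <- target
  tibble::as_tibble(out)
}

#' Synthetic subject profile
#'
#' Encapsulates one simulated participant: a common condition-plateau table
#' scaled by an individual responsiveness multiplier, a rise time constant,
#' residual tracking-error noise, and a constant bar-offset (random
#' intercept, removed downstream by rebasing).
#'
#' @param plateaus Tibble from [plateau_preset()] (columns `velocity`,
#'   `noise`, `plateau_deg`).
#' @param tau Rise time constant (s), > 0.
#' @param responsiveness Individual multiplier on all plateaus, >= 0.
#' @param tracking_sd SD (degrees) of the residual (un-corrected) bar noise.
#' @param intercept Constant bar-angle offset (degrees).
#' @return An object of class `svv_subject`.
#' @export
subject_profile <- function(plateaus = plateau_preset(), tau = 11.4,
                            responsiveness = 1, tracking_sd = 2,
                            intercept = 0) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (responsiveness < 0) stop("responsiveness must be >= 0", call. = FALSE)
  structure(list(plateaus = plateaus, tau = tau,
                 responsiveness = responsiveness,
                 tracking_sd = tracking_sd, intercept = intercept),
            class = "svv_subject")
}

# first-order low-pass (bilinear alpha) of a series; models the part of the
# injected bar noise the subject fails to correct
lowpass1 <- function(x, fc, fs) {
  alpha <- (2 * pi * fc / fs) / (1 + 2 * pi * fc / fs)
  stats::filter(alpha * x, 1 - alpha, method = "recursive", init = 0)
}

#' Generate one synthetic bar-angle trial
#'
#' The trace is the sum of (i) a random starting offset (uniform on +/-45
#' degrees) corrected with a fast exponential settle, (ii) a signed
#' exponential bias rise `a (1 - exp(-(t - 10)/tau))` during the 30-s motion
#' period (decaying with the same `tau` afterwards), with amplitude
#' `a = plateau x responsiveness` and sign set by the rotation direction,
#' (iii) residual tracking noise (a first-order low-pass of a band-limited
#' bar-noise realization, rescaled to `tracking_sd`), and (iv) the subject's
#' constant offset. All stochastic components flip sign with direction, so
#' same-seed clockwise/counter-clockwise traces are exact mirror images
#' (up to the direction-invariant intercept).
#'
#' @param profile [subject_profile()].
#' @param velocity,noise Condition (deg/s, fraction).
#' @param direction `"ccw"` or `"cw"`.
#' @param bar_noise [bar_noise_spec()] injected on the bar.
#' @param dt Sample interval (s), default 1/30.
#' @param duration_s Trial length (s), default 50.
#' @param settle_tau Settle time constant (s) for the initial offset.
#' @return Tibble with columns `time`, `bar_angle` (1500 rows at defaults).
#' @export
generate_trial <- function(profile, velocity, noise,
                           direction = c("ccw", "cw"),
                           bar_noise = bar_noise_spec(), dt = 1 / 30,
                           duration_s = 50, settle_tau = 0.5) {
  direction <- match.arg(direction)
  stopifnot(inherits(profile, "svv_subject"))
  time <- (seq_len(round(duration_s / dt)) - 1) * dt
  angle <- trial_components(profile, velocity, noise, direction, bar_noise,
                            time, settle_tau)
  tibble::tibble(time = time, bar_angle = angle)
}

trial_components <- function(profile, velocity, noise, direction, bar_noise,
                             time, settle_tau = 0.5,
                             onset = 10, offset_t = 40) {
  row <- profile$plateaus$velocity == velocity & profile$plateaus$noise == noise
  if (!any(row)) {
    stop(sprintf("condition (%g deg/s, %g noise) not in the plateau table",
                 velocity, noise), call. = FALSE)
  }
  a <- profile$plateaus$plateau_deg[which(row)[1]] * profile$responsiveness
  tau <- profile$tau
  sgn <- if (direction == "ccw") 1 else -1

  u0 <- stats::runif(1, -45, 45)
  settle <- u0 * exp(-time / settle_tau)

  bias <- numeric(length(time))
  rising <- time >= onset & time < offset_t
  bias[rising] <- a * (1 - exp(-(time[rising] - onset) / tau))
  post <- time >= offset_t
  b_end <- a * (1 - exp(-(offset_t - onset) / tau))
  bias[post] <- b_end * exp(-(time[post] - offset_t) / tau)

  resid <- numeric(length(time))
  if (profile$tracking_sd > 0) {
    injected <- generate_bar_noise(bar_noise, duration_s = max(time) + time[2])
    injected <- injected[seq_along(time)]
    r <- as.numeric(lowpass1(injected, fc = 0.1, fs = 1 / (time[2] - time[1])))
    s <- stats::sd(r)
    if (s > 0) r <- r * profile$tracking_sd / s
    resid <- r
  } else {
    u0 <- 0
    settle <- numeric(length(time))
  }
  sgn * (settle + bias + resid) + profile$intercept
}

#' Generate a synthetic cohort of bar-angle trials
#'
#' Draws per-subject responsiveness multipliers (lognormal, mean 1) and
#' random intercepts, builds a randomized schedule per subject, and
#' generates every trial. Traces are stored compactly as a trials-by-samples
#' matrix alongside a metadata table (see [trials_as_tibble()] for the tidy
#' long form).
#'
#' @param n_subjects Cohort size (default 10, the original sample size).
#' @param preset Plateau preset passed to [plateau_preset()].
#' @param tau Rise time constant (s).
#' @param tracking_sd Residual tracking-noise SD (degrees).
#' @param responsiveness_sdlog Between-subject lognormal sdlog of the
#'   responsiveness multiplier (0 disables individual differences).
#' @param intercept_sd SD (degrees) of the subject random intercept.
#' @param grid [design_grid()].
#' @param dt Sample interval (s).
#' @return An object of class `svv_trials`: list with `meta` (tibble:
#'   subject, session, trial, velocity, noise, direction), `angle`
#'   (matrix, one row per trial), `time`, and `profiles`.
#' @export
generate_cohort <- function(n_subjects = 10, preset = "table1", tau = 11.4,
                            tracking_sd = 2, responsiveness_sdlog = 0.15,
                            intercept_sd = 2, grid = design_grid(),
                            dt = 1 / 30) {
  plateaus <- plateau_preset(preset, tau = tau)
  time <- (seq_len(round(50 / dt)) - 1) * dt
  meta_list <- vector("list", n_subjects)
  ang_list <- vector("list", n_subjects)
  profiles <- vector("list", n_subjects)
  bn <- bar_noise_spec()
  for (s in seq_len(n_subjects)) {
    resp <- if (responsiveness_sdlog > 0) {
      stats::rlnorm(1, meanlog = -responsiveness_sdlog^2 / 2,
                    sdlog = responsiveness_sdlog)
    } else 1
    prof <- subject_profile(plateaus, tau = tau, responsiveness = resp,
                            tracking_sd = tracking_sd,
                            intercept = stats::rnorm(1, 0, intercept_sd))
    sched <- build_schedule(grid)
    ang <- matrix(0, nrow(sched), length(time))
    for (i in seq_len(nrow(sched))) {
      ang[i, ] <- trial_components(prof, sched$velocity[i], sched$noise[i],
                                   sched$direction[i], bn, time)
    }
    meta_list[[s]] <- tibble::tibble(subject = s, sched)
    ang_list[[s]] <- ang
    profiles[[s]] <- prof
  }
  structure(list(meta = dplyr::bind_rows(meta_list),
                 angle = do.call(rbind, ang_list),
                 time = time, profiles = profiles),
            class = "svv_trials")
}

#' @exportS3Method base::print
print.svv_trials <- function(x, ...) {
  cat(sprintf("svv_trials: %d trials x %d samples, %d subject(s)\n",
              nrow(x$angle), ncol(x$angle), length(unique(x$meta$subject))))
  invisible(x)
}

#' Tidy long form of a trial set
#'
#' @param trials An `svv_trials` object.
#' @return Tibble with one row per sample: subject, session, trial,
#'   velocity, noise, direction, time, bar_angle.
#' @export
trials_as_tibble <- function(trials) {
  stopifnot(inherits(trials, "svv_trials"))
  n_t <- length(trials$time)
  meta <- trials$meta[rep(seq_len(nrow(trials$meta)), each = n_t), ]
  tibble::tibble(meta,
                 time = rep(trials$time, nrow(trials$angle)),
                 bar_angle = as.vector(t(trials$angle)))
}

#' Generate a synthetic two-alternative forced-choice dataset
#'
#' Each subject judges, 16 times per cell of a 7-velocity x 4-noise
#' comparison grid, whether the comparison stimulus is faster than a 6 deg/s
#' noise-free reference. The probability of responding "faster" follows a
#' cumulative Gaussian of the signed difference between the comparison
#' velocity and the subject's point of subjective equality (PSE) at that
#' noise level, with `PSE = pse_intercept + (pse_slope + b_s) * noise` and a
#' per-subject random slope `b_s`.
#'
#' @param n_subjects Number of subjects (default 8, the original control
#'   sample size).
#' @param pse_intercept PSE at zero noise (deg/s).
#' @param pse_slope Mean PSE change per unit noise fraction (deg/s).
#' @param slope_sd SD of the per-subject random slope (deg/s per unit noise).
#' @param psychometric_sd Slope parameter of the cumulative Gaussian (deg/s).
#' @param lapse Lapse rate (probability of a random response).
#' @param velocities Comparison velocities (deg/s).
#' @param noise_levels Comparison noise fractions.
#' @param reps Repetitions per cell.
#' @return Tibble with columns `subject`, `velocity`, `noise`, `order`
#'   (1 = comparison first), `response` (`"faster"`/`"slower"`), plus the
#'   generating subject PSE in attribute `"generating_pse"`.
#' @export
generate_2afc_dataset <- function(n_subjects = 8, pse_intercept = 6,
                                  pse_slope = -1.6, slope_sd = 0.5,
                                  psychometric_sd = 1, lapse = 0.02,
                                  velocities = 3:9,
                                  noise_levels = c(0, 0.2, 0.4, 0.6),
                                  reps = 16) {
  stopifnot(n_subjects >= 1)
  rows <- vector("list", n_subjects)
  gen_pse <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    b_s <- stats::rnorm(1, 0, slope_sd)
    cells <- expand.grid(velocity = velocities, noise = noise_levels,
                         rep = seq_len(reps), KEEP.OUT.ATTRS = FALSE)
    cells <- cells[sample.int(nrow(cells)), ]
    pse <- pse_intercept + (pse_slope + b_s) * cells$noise
    p_faster <- lapse / 2 +
      (1 - lapse) * stats::pnorm((cells$velocity - pse) / psychometric_sd)
    resp <- ifelse(stats::runif(nrow(cells)) < p_faster, "faster", "slower")
    rows[[s]] <- tibble::tibble(subject = s, velocity = cells$velocity,
                                noise = cells$noise,
                                order = sample(1:2, nrow(cells), TRUE),
                                response = resp)
    gen_pse[[s]] <- tibble::tibble(
      subject = s, noise = noise_levels,
      pse = pse_intercept + (pse_slope + b_s) * noise_levels)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "generating_pse") <- dplyr::bind_rows(gen_pse)
  out
}
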