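#' Rebase a bar-angle trace to its 5-10 s baseline
#'
#' Subtracts the trace's mean over the 5-10 s static baseline from every
#' sample, so that slow per-trial offsets (starting position, subject
#' intercept) are removed before analysis.
#'
#' @param angle Numeric trace (degrees).
#' @param time Matching time grid (s); must cover `[5, 10]`.
#' @param baseline Baseline window (s), default `c(5, 10)` (closed).
#' @return The rebased trace.
#' @export
rebase_trace <- function(angle, time, baseline = c(5, 10)) {
  idx <- time >= baseline[1] & time <= baseline[2]
  if (!any(idx)) stop("trace does not cover the baseline window",
                      call. = FALSE)
  angle - mean(angle[idx])
}

#' Mean bar angle over the analysis window
#'
#' @param angle Numeric trace (degrees, typically rebased).
#' @param time Matching time grid (s); must cover the window.
#' @param window Analysis window (s), default `c(27, 40)` (closed bounds on
#'   the 30 Hz grid).
#' @return Scalar mean (degrees).
#' @export
window_mean <- function(angle, time, window = c(27, 40)) {
  idx <- time >= window[1] & time <= window[2]
  if (!any(idx)) stop("trace does not cover the analysis window",
                      call. = FALSE)
  mean(angle[idx])
}

# rebased angle matrix for an svv_trials object
rebase_trials <- function(trials, baseline = c(5, 10)) {
  idx <- trials$time >= baseline[1] & trials$time <= baseline[2]
  if (!any(idx)) stop("trials do not cover the baseline window",
                      call. = FALSE)
  trials$angle - rowMeans(trials$angle[, idx, drop = FALSE])
}

#' Per-condition clockwise vs counter-clockwise comparison
#'
#' For each feasible condition, compares the absolute rebased window means
#' of clockwise and counter-clockwise trials across subjects with a paired
#' t-test. The significance threshold is Bonferroni-corrected for the
#' number of conditions (0.05 / 33 = 0.0015 at the default design).
#'
#' @param trials An `svv_trials` object.
#' @param alpha Familywise error rate before correction.
#' @param window Analysis window (s).
#' @return Tibble with columns `velocity`, `noise`, `t`, `df`, `p`,
#'   `threshold`, `significant`.
#' @export
direction_test <- function(trials, alpha = 0.05, window = c(27, 40)) {
  stopifnot(inherits(trials, "svv_trials"))
  reb <- rebase_trials(trials)
  wm_idx <- trials$time >= window[1] & trials$time <= window[2]
  wm <- rowMeans(reb[, wm_idx, drop = FALSE])
  d <- dplyr::mutate(trials$meta, wm = wm)
  per_subj <- dplyr::summarise(
    dplyr::group_by(d, .data$subject, .data$velocity, .data$noise,
                    .data$direction),
    awm = mean(abs(.data$wm)), .groups = "drop")
  wide <- tidyr::pivot_wider(per_subj, names_from = "direction",
                             values_from = "awm")
  conds <- dplyr::distinct(wide, .data$velocity, .data$noise)
  thr <- alpha / nrow(conds)
  res <- lapply(seq_len(nrow(conds)), function(i) {
    sub <- wide[wide$velocity == conds$velocity[i] &
                  wide$noise == conds$noise[i], ]
    if (nrow(sub) < 2) stop("need >= 2 subjects for the paired test",
                            call. = FALSE)
    diffs <- sub$cw - sub$ccw
    if (stats::sd(diffs) == 0) {
      tt <- list(statistic = 0, parameter = nrow(sub) - 1, p.value = 1)
    } else {
      tt <- stats::t.test(sub$cw, sub$ccw, paired = TRUE)
    }
    tibble::tibble(velocity = conds$velocity[i], noise = conds$noise[i],
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, threshold = thr,
                   significant = tt$p.value < thr)
  })
  dplyr::bind_rows(res)
}

#' Fold directions and average trials within subject and condition
#'
#' Rebases every trial, inverts (sign-flips) the clockwise traces, and
#' averages all trials pointwise within each subject x condition; the
#' window mean is computed from the folded trace. Conditions absent from
#' the data (the omitted design cells) are simply absent from the output.
#'
#' @param trials An `svv_trials` object.
#' @param window Analysis window (s).
#' @return An object of class `svv_condition_summary`: list with `meta`
#'   (tibble: subject, velocity, noise, n_trials, window_mean_deg), `trace`
#'   (matrix of folded mean traces, row-aligned with `meta`), `time`.
#' @export
fold_average <- function(trials, window = c(27, 40)) {
  stopifnot(inherits(trials, "svv_trials"))
  if (nrow(trials$meta) == 0) stop("no trials", call. = FALSE)
  reb <- rebase_trials(trials)
  sgn <- ifelse(trials$meta$direction == "cw", -1, 1)
  folded <- reb * sgn
  key <- paste(trials$meta$subject, trials$meta$velocity, trials$meta$noise,
               sep = "\r")
  groups <- split(seq_len(nrow(folded)), key)
  meta <- trials$meta[vapply(groups, `[`, integer(1), 1), ]
  trace <- t(vapply(groups, function(ix) {
    colMeans(folded[ix, , drop = FALSE])
  }, numeric(ncol(folded))))
  wm_idx <- trials$time >= window[1] & trials$time <= window[2]
  out_meta <- tibble::tibble(subject = meta$subject,
                             velocity = meta$velocity, noise = meta$noise,
                             n_trials = unname(lengths(groups)),
                             window_mean_deg = unname(
                               rowMeans(trace[, wm_idx, drop = FALSE])))
  ord <- order(out_meta$subject, out_meta$velocity, out_meta$noise)
  structure(list(meta = out_meta[ord, ], trace = trace[ord, , drop = FALSE],
                 time = trials$time),
            class = "svv_condition_summary")
}

#' Grand-mean folded traces across subjects
#'
#' @param summary An `svv_condition_summary` from [fold_average()].
#' @return A list with `meta` (tibble: velocity, noise, n_subjects,
#'   window_mean_deg), `trace` (condition x time matrix of across-subject
#'   mean traces), `time`.
#' @export
grand_mean_traces <- function(summary) {
  stopifnot(inherits(summary, "svv_condition_summary"))
  key <- paste(summary$meta$velocity, summary$meta$noise, sep = "\r")
  groups <- split(seq_len(nrow(summary$trace)), key)
  first <- vapply(groups, `[`, integer(1), 1)
  trace <- t(vapply(groups, function(ix) {
    colMeans(summary$trace[ix, , drop = FALSE])
  }, numeric(ncol(summary$trace))))
  meta <- tibble::tibble(velocity = unname(summary$meta$velocity[first]),
                         noise = unname(summary$meta$noise[first]),
                         n_subjects = unname(lengths(groups)),
                         window_mean_deg = unname(
                           vapply(groups, function(ix) {
                             mean(summary$meta$window_mean_deg[ix])
                           }, numeric(1))))
  ord <- order(meta$velocity, meta$noise)
  list(meta = meta[ord, ], trace = trace[ord, , drop = FALSE],
       time = summary$time)
}

#' Fit a saturating exponential to a bias trace
#'
#' Nonlinear least squares of `Y = a (1 - exp(-b x)) + c`, with `x` the time
#' since motion onset, over the motion window. The time constant `tau = 1/b`
#' is the time for the rise to reach 63.2% of its height. Uses
#' Levenberg-Marquardt with a small multi-start ladder; non-convergence is
#' reported via `converged = FALSE`, never as an exception.
#'
#' @param angle Trace (degrees).
#' @param time Trial time grid (s).
#' @param onset Motion onset (s of trial time); `x = time - onset`.
#' @param window Fit window in trial time (s), default `c(10, 40)`.
#' @param n_starts Number of jittered restarts after the deterministic
#'   start.
#' @return An object of class `svv_expfit`: list with `a`, `b`, `c`, `tau`
#'   (NA unless `b > 0`), `sse`, `r_squared`, `converged`.
#' @export
fit_exponential <- function(angle, time, onset = 10, window = c(10, 40),
                            n_starts = 5) {
  idx <- time >= window[1] & time <= window[2]
  if (!any(idx)) stop("trace does not cover the fit window", call. = FALSE)
  x <- time[idx] - onset
  y <- angle[idx]

  a0 <- mean(y[x >= max(x) - 2])
  starts <- list(c(a = a0, b = 1 / 10, c = 0))
  for (j in seq_len(n_starts)) {
    starts[[j + 1]] <- c(a = a0 * stats::runif(1, 0.5, 2) +
                           stats::rnorm(1, 0, 0.1),
                         b = 1 / stats::runif(1, 2, 30),
                         c = stats::rnorm(1, 0, 0.5))
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * (1 - exp(-b * x)) + c,
                        start = as.list(st),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) {
      cf <- stats::coef(fit)
      best <- list(a = unname(cf["a"]), b = unname(cf["b"]),
                   c = unname(cf["c"]), sse = sse)
    }
  }
  ss_tot <- sum((y - mean(y))^2)
  if (is.null(best)) {
    return(structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                          tau = NA_real_, sse = NA_real_,
                          r_squared = NA_real_, converged = FALSE),
                     class = "svv_expfit"))
  }
  flat <- abs(best$a) < 1e-8 || ss_tot == 0
  structure(list(a = best$a, b = best$b, c = best$c,
                 tau = if (!flat && best$b > 0) 1 / best$b else NA_real_,
                 sse = best$sse,
                 r_squared = if (ss_tot > 0) 1 - best$sse / ss_tot
                 else NA_real_,
                 converged = TRUE),
            class = "svv_expfit")
}

#' @exportS3Method base::print
print.svv_expfit <- function(x, ...) {
  cat(sprintf(
    "exponential fit: a = %.4g, b = %.4g 1/s, c = %.4g; tau = %.4g s (r2 = %.4f)\n",
    x$a, x$b, x$c, x$tau, x$r_squared))
  invisible(x)
}

#' Write condition summaries to CSV
#'
#' @param summary An `svv_condition_summary`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  utils::write.csv(summary$meta, path, row.names = FALSE)
  invisible(path)
}
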