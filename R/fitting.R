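#' Predicted bias traces for every feasible design condition
#'
#' Simulates the mechanistic model over the standard 10 s static / 30 s
#' motion / 10 s static protocol for each feasible (velocity, noise) cell,
#' applying the visual-gain noise attenuation before simulating.
#'
#' @param params [model_params()].
#' @param grid [design_grid()].
#' @param dt Integration/sampling step (s).
#' @return List with `meta` (tibble: velocity, noise), `trace` (condition x
#'   time matrix of bias, degrees), `time`.
#' @export
predict_bias_traces <- function(params = model_params(),
                                grid = design_grid(), dt = 1 / 30) {
  cond <- feasible_conditions(grid)
  proto <- roll_protocol(1, dt = dt)  # template; vis scaled per condition
  n <- length(proto$time)
  trace <- matrix(0, nrow(cond), n)
  for (i in seq_len(nrow(cond))) {
    pp <- apply_noise_attenuation(params, cond$noise[i])
    pr <- roll_protocol(cond$velocity[i], dt = dt)
    trace[i, ] <- svv_simulate(pr, pp)$bias
  }
  list(meta = cond, trace = trace, time = proto$time)
}

#' Sum of squared error between predicted and observed bias
#'
#' Squared prediction error summed over all shared conditions and, by
#' default, over every 30 Hz sample of the motion period (10-40 s of trial
#' time). With `granularity = "window_mean"` the error is computed on the
#' 27-40 s window means instead.
#'
#' @param params [model_params()].
#' @param observed List as produced by [grand_mean_traces()] (or
#'   [predict_bias_traces()]): `meta` with `velocity`, `noise`; `trace`;
#'   `time`.
#' @param grid Design grid restricted to the observed conditions.
#' @param granularity `"trace"` or `"window_mean"`.
#' @param dt Integration step (s).
#' @return Scalar SSE (degrees^2).
#' @export
model_sse <- function(params, observed, grid = design_grid(),
                      granularity = c("trace", "window_mean"),
                      dt = 1 / 30) {
  granularity <- match.arg(granularity)
  pred <- predict_bias_traces(params, grid, dt = dt)
  key_o <- paste(observed$meta$velocity, observed$meta$noise)
  key_p <- paste(pred$meta$velocity, pred$meta$noise)
  if (!setequal(key_o, key_p) || anyDuplicated(key_o)) {
    stop("observed and predicted conditions do not match", call. = FALSE)
  }
  m <- match(key_o, key_p)
  if (granularity == "trace") {
    idx <- pred$time >= 10 & pred$time <= 40
    oidx <- observed$time >= 10 & observed$time <= 40
    if (sum(idx) != sum(oidx)) {
      stop("observed and predicted time grids do not match", call. = FALSE)
    }
    sum((pred$trace[m, idx, drop = FALSE] -
           observed$trace[, oidx, drop = FALSE])^2)
  } else {
    widx <- pred$time >= 27 & pred$time <= 40
    pw <- rowMeans(pred$trace[m, widx, drop = FALSE])
    ow <- rowMeans(observed$trace[, observed$time >= 27 &
                                    observed$time <= 40, drop = FALSE])
    sum((pw - ow)^2)
  }
}

#' Coefficient of determination between an observed and a predicted trace
#'
#' `1 - SS_res / SS_tot`, with `SS_tot` taken about the observed mean.
#' Returns `NA` (with a warning) for a zero-variance observed trace.
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @return Scalar r-squared (<= 1), or `NA` if undefined.
#' @export
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length", call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warning("zero-variance observed trace: r-squared undefined")
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Fit the mechanistic model to condition-mean bias data
#'
#' Bounded local optimisation (L-BFGS-B) of the selected free parameters by
#' SSE minimisation, with multi-start: the supplied initial values plus
#' `n_starts` starts drawn log-uniform within the bounds. Free parameters
#' whose gradient at the solution is numerically zero (e.g. the vestibular
#' gains when the canal signal is zero throughout, as in the seated
#' protocol) trigger a sensitivity warning in the result.
#'
#' @param observed As in [model_sse()].
#' @param free Character vector naming the free parameters, a subset of
#'   `c("ko", "kv", "go", "gv", "t_s")`. `t_vs` stays fixed at 15 s and
#'   `kf` at 0 unless changed via `fixed`.
#' @param fixed [model_params()] providing every non-free value.
#' @param lower,upper Named bounds for the free parameters (defaults:
#'   gains in `[0, 5]`, `t_s` in `[0.05, 60]` s).
#' @param init Named starting values (defaults to the values in `fixed`).
#' @param n_starts Additional random starts (default 10).
#' @param granularity,grid,dt Passed to [model_sse()].
#' @return An object of class `svv_fit`: list with `params` (full fitted
#'   parameter set), `estimates`, `sse`, `r_squared` (per-condition tibble),
#'   `convergence`, `warnings`, `starts_tried`.
#' @export
fit_svv_model <- function(observed, free = c("ko", "go", "t_s"),
                          fixed = model_params(),
                          lower = NULL, upper = NULL, init = NULL,
                          n_starts = 10,
                          granularity = "trace", grid = design_grid(),
                          dt = 1 / 30) {
  allowed <- c("ko", "kv", "go", "gv", "t_s")
  if (!all(free %in% allowed)) {
    stop("free parameters must be a subset of: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  default_lower <- c(ko = 0, kv = 0, go = 0, gv = 0, t_s = 0.05)
  default_upper <- c(ko = 5, kv = 5, go = 5, gv = 5, t_s = 60)
  lo <- default_lower[free]; hi <- default_upper[free]
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  th0 <- unlist(fixed[free])
  if (!is.null(init)) th0[names(init)] <- init
  if (any(th0 < lo | th0 > hi)) {
    stop("initial values must lie within the bounds", call. = FALSE)
  }

  obj <- function(th) {
    p <- fixed
    p[free] <- as.list(th)
    model_sse(p, observed, grid = grid, granularity = granularity, dt = dt)
  }

  starts <- list(th0)
  lo_pos <- pmax(lo, 1e-3)
  for (j in seq_len(n_starts)) {
    starts[[j + 1]] <- stats::setNames(
      exp(stats::runif(length(free), log(lo_pos), log(hi))), free)
  }

  best <- NULL
  n_ok <- 0
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500, factr = 10,
                                  parscale = pmax(abs(st), 1e-2))),
      error = function(e) NULL)
    if (is.null(res)) next
    n_ok <- n_ok + 1
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, estimates = NULL, sse = NA_real_,
                          r_squared = NULL, convergence = NA_integer_,
                          warnings = "all optimisation starts failed",
                          starts_tried = length(starts)),
                     class = "svv_fit"))
  }

  th <- best$par
  params <- fixed
  params[free] <- as.list(th)

  # zero-sensitivity check: relative central differences at the solution
  warnings <- character(0)
  f0 <- best$value
  for (k in seq_along(free)) {
    h <- pmax(abs(th[k]), 0.1) * 1e-3
    up <- th; up[k] <- min(th[k] + h, hi[k])
    dn <- th; dn[k] <- max(th[k] - h, lo[k])
    if (abs(obj(up) - obj(dn)) <= 1e-12 * max(1, f0)) {
      warnings <- c(warnings, sprintf(
        "parameter '%s' has zero sensitivity (flat objective)", free[k]))
    }
  }

  pred <- predict_bias_traces(params, grid, dt = dt)
  key_o <- paste(observed$meta$velocity, observed$meta$noise)
  key_p <- paste(pred$meta$velocity, pred$meta$noise)
  m <- match(key_o, key_p)
  idx <- pred$time >= 10 & pred$time <= 40
  oidx <- observed$time >= 10 & observed$time <= 40
  r2 <- vapply(seq_along(m), function(i) {
    suppressWarnings(r_squared(pred$trace[m[i], idx],
                               observed$trace[i, oidx]))
  }, numeric(1))

  structure(list(params = params,
                 estimates = stats::setNames(as.numeric(th), free),
                 sse = best$value,
                 r_squared = tibble::tibble(velocity = observed$meta$velocity,
                                            noise = observed$meta$noise,
                                            r2 = r2),
                 convergence = best$convergence,
                 warnings = warnings,
                 starts_tried = length(starts), starts_converged = n_ok),
            class = "svv_fit")
}

#' @exportS3Method base::print
print.svv_fit <- function(x, ...) {
  cat("Mechanistic model fit (SSE minimisation)\n")
  if (is.null(x$params)) {
    cat("  FAILED:", x$warnings, "\n")
    return(invisible(x))
  }
  est <- paste(sprintf("%s = %.4g", names(x$estimates), x$estimates),
               collapse = ", ")
  cat("  ", est, "\n", sep = "")
  cat(sprintf("  SSE = %.6g over %d conditions; median r2 = %.3f\n",
              x$sse, nrow(x$r_squared),
              stats::median(x$r_squared$r2, na.rm = TRUE)))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
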