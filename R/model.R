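#' @useDynLib svvbias, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

DEG2RAD <- pi / 180

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Retinal slip
#'
#' The angular velocity of the visual scene relative to the retina: the
#' difference between the scene velocity and the inferred head velocity.
#'
#' @param vis 3-vector scene angular velocity (deg/s).
#' @param omega 3-vector inferred head angular velocity (deg/s).
#' @return 3-vector retinal slip (deg/s).
#' @export
retinal_slip <- function(vis, omega) {
  if (!is.numeric(vis) || !is.numeric(omega) ||
      length(vis) != 3L || length(omega) != 3L ||
      !all(is.finite(vis)) || !all(is.finite(omega))) {
    stop("vis and omega must be finite 3-vectors", call. = FALSE)
  }
  vis - omega
}

#' Inferred head angular velocity
#'
#' Resolves the direct visual pathway algebraically: with
#' `Omega = go*rSL + gv*V + VS` and `rSL = Vis - Omega`, the self-consistent
#' solution is `Omega = (go*Vis + gv*V + VS) / (1 + go)`.
#'
#' @param vis,v,vs 3-vectors: scene velocity, canal signal, storage content
#'   (all deg/s).
#' @param params [model_params()].
#' @return 3-vector inferred head velocity (deg/s).
#' @export
infer_omega <- function(vis, v, vs, params) {
  (params$go * vis + params$gv * v + vs) / (1 + params$go)
}

#' Model state
#'
#' @param vs 3-vector velocity-storage content (deg/s).
#' @param g 3-vector internal gravity-direction estimate (unit length).
#' @param t Elapsed time (s).
#' @return An object of class `svv_state`.
#' @export
model_state <- function(vs = c(0, 0, 0), g = c(0, 0, 1), t = 0) {
  stopifnot(length(vs) == 3L, length(g) == 3L)
  nrm <- sqrt(sum(g^2))
  if (abs(nrm - 1) > 1e-3) {
    stop("|g| must be within 1e-3 of 1", call. = FALSE)
  }
  structure(list(vs = as.numeric(vs), g = as.numeric(g), t = t),
            class = "svv_state")
}

state_deriv <- function(vs, g, vis, v, gia, params) {
  omega <- infer_omega(vis, v, vs, params)
  rsl <- vis - omega
  dvs <- params$ko * rsl + params$kv * v - vs / params$t_vs +
    params$kf * cross3(gia, g)
  dg <- cross3(g, omega * DEG2RAD) - (g - gia) / params$t_s
  # G is a direction estimate: drop the radial part of its derivative so
  # the flow stays on the unit sphere (the tangential dynamics, and hence
  # the bias, are unchanged)
  dg <- dg - sum(dg * g) / sum(g * g) * g
  list(dvs = dvs, dg = dg, omega = omega)
}

#' Advance the state estimator by one time step
#'
#' One classical fourth-order Runge-Kutta step of the coupled
#' velocity-storage / gravity-estimate system, with the input sample held
#' constant across the step. The gravity estimate is renormalised to unit
#' length afterwards. This is the reference (pure R) integrator; full
#' trajectories use a compiled equivalent via [svv_simulate()].
#'
#' @param state An [model_state()].
#' @param input A list with 3-vectors `vis`, `v`, `gia` (the sample of the
#'   motion input at the current time).
#' @param params [model_params()].
#' @param dt Step size (s), must be positive.
#' @return The advanced `svv_state`.
#' @export
svv_step <- function(state, input, params, dt) {
  stopifnot(inherits(state, "svv_state"), inherits(params, "svv_params"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a positive scalar", call. = FALSE)
  }
  vis <- input$vis; v <- input$v; gia <- input$gia
  if (any(!is.finite(c(vis, v, gia)))) {
    stop("non-finite input sample", call. = FALSE)
  }
  k1 <- state_deriv(state$vs, state$g, vis, v, gia, params)
  k2 <- state_deriv(state$vs + dt / 2 * k1$dvs, state$g + dt / 2 * k1$dg,
                    vis, v, gia, params)
  k3 <- state_deriv(state$vs + dt / 2 * k2$dvs, state$g + dt / 2 * k2$dg,
                    vis, v, gia, params)
  k4 <- state_deriv(state$vs + dt * k3$dvs, state$g + dt * k3$dg,
                    vis, v, gia, params)
  vs <- state$vs + dt / 6 * (k1$dvs + 2 * k2$dvs + 2 * k3$dvs + k4$dvs)
  g <- state$g + dt / 6 * (k1$dg + 2 * k2$dg + 2 * k3$dg + k4$dg)
  g <- g / sqrt(sum(g^2))
  model_state(vs = vs, g = g, t = state$t + dt)
}

#' Build a roll-plane motion protocol
#'
#' Constructs the motion-input series for the standard trial: a static
#' pre-period, constant-velocity roll rotation of the visual scene about the
#' naso-occipital (x) axis, and a static post-period. The head is stationary
#' (canal signal zero) and the gravito-inertial direction is fixed at
#' (0, 0, 1).
#'
#' @param velocity_deg_s Scene rotation speed (deg/s, non-negative).
#' @param direction `"ccw"` (positive roll) or `"cw"`.
#' @param static_pre_s,motion_s,static_post_s Segment durations (s).
#' @param dt Sample interval (s); default 1/30 (the 30 Hz recording grid).
#' @return An object of class `svv_protocol`: list with `time`, and n x 3
#'   matrices `vis`, `v`, `gia`.
#' @export
roll_protocol <- function(velocity_deg_s, direction = c("ccw", "cw"),
                          static_pre_s = 10, motion_s = 30,
                          static_post_s = 10, dt = 1 / 30) {
  direction <- match.arg(direction)
  stopifnot(velocity_deg_s >= 0, dt > 0)
  duration <- static_pre_s + motion_s + static_post_s
  if (duration <= 0) stop("empty protocol", call. = FALSE)
  n <- round(duration / dt)
  time <- (seq_len(n) - 1) * dt
  sgn <- if (direction == "ccw") 1 else -1
  moving <- time >= static_pre_s & time < static_pre_s + motion_s
  vis <- matrix(0, n, 3)
  vis[moving, 1] <- sgn * velocity_deg_s
  v <- matrix(0, n, 3)
  gia <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  structure(list(time = time, vis = vis, v = v, gia = gia, dt = dt,
                 velocity_deg_s = velocity_deg_s, direction = direction,
                 motion_window = c(static_pre_s, static_pre_s + motion_s)),
            class = "svv_protocol")
}

#' Arbitrary motion protocol
#'
#' Lower-level constructor when the three input series are supplied directly.
#'
#' @param time Time grid (s), uniformly spaced.
#' @param vis,v,gia n x 3 matrices: scene velocity, canal signal (deg/s) and
#'   unit GIA direction at each sample.
#' @return An `svv_protocol` object.
#' @export
motion_input <- function(time, vis, v = NULL, gia = NULL) {
  n <- length(time)
  if (n < 2) stop("empty protocol", call. = FALSE)
  vis <- as.matrix(vis)
  if (is.null(v)) v <- matrix(0, n, 3)
  if (is.null(gia)) gia <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  stopifnot(nrow(vis) == n, nrow(v) == n, nrow(gia) == n)
  nrm <- sqrt(rowSums(gia^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("|gia| must be 1 at every sample",
                                     call. = FALSE)
  dt <- time[2] - time[1]
  structure(list(time = time, vis = vis, v = v, gia = gia, dt = dt,
                 motion_window = range(time)),
            class = "svv_protocol")
}

#' Simulate the verticality-perception model over a protocol
#'
#' Integrates the coupled velocity-storage / gravity-estimate system over the
#' full protocol, starting from `G(0) = GIA(0)` and `VS(0) = 0`. The reported
#' `bias` is the signed roll-plane angle between the gravity estimate and the
#' GIA direction (degrees, positive in the direction of positive roll, i.e.
#' counter-clockwise scene rotation).
#'
#' @param protocol An `svv_protocol` (see [roll_protocol()]).
#' @param params [model_params()].
#' @param dt Integration step (s); defaults to the protocol's sample interval.
#'   When `dt` is smaller than the protocol interval the input series is
#'   resampled by piecewise-constant interpolation and the output is returned
#'   on the fine grid.
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   stepping via [svv_step()]).
#' @return An object of class `svv_sim`: a list with the time grid, the
#'   `g`, `vs`, `omega` trajectories (n x 3), the inferred linear
#'   acceleration `a_hat = gia - g`, the signed `bias` in degrees, and the
#'   worst unit-norm drift of `g` observed before renormalisation.
#' @export
svv_simulate <- function(protocol, params = model_params(), dt = NULL,
                         engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(protocol, "svv_protocol"),
            inherits(params, "svv_params"))
  if (is.null(dt)) dt <- protocol$dt
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)

  time <- protocol$time
  vis <- protocol$vis; v <- protocol$v; gia <- protocol$gia
  if (abs(dt - protocol$dt) > 1e-12) {
    # piecewise-constant resampling onto the requested grid
    t_new <- seq(time[1], time[length(time)], by = dt)
    idx <- findInterval(t_new + 1e-12, time)
    vis <- vis[idx, , drop = FALSE]
    v <- v[idx, , drop = FALSE]
    gia <- gia[idx, , drop = FALSE]
    time <- t_new
  }

  g0 <- gia[1, ]
  vs0 <- c(0, 0, 0)
  if (engine == "cpp") {
    out <- .sim_core_cpp(vis, v, gia, vs0, g0,
                         params$ko, params$kv, params$go, params$gv,
                         params$kf, params$t_vs, params$t_s, dt)
    g <- out$g; vs <- out$vs; omega <- out$omega
    max_drift <- out$max_drift
  } else {
    n <- length(time)
    g <- vs <- omega <- matrix(0, n, 3)
    st <- model_state(vs = vs0, g = g0, t = time[1])
    max_drift <- 0
    for (i in seq_len(n)) {
      input <- list(vis = vis[i, ], v = v[i, ], gia = gia[i, ])
      g[i, ] <- st$g
      vs[i, ] <- st$vs
      omega[i, ] <- infer_omega(vis[i, ], v[i, ], st$vs, params)
      if (i < n) st <- svv_step(st, input, params, dt)
    }
  }
  bias <- signed_roll_bias(g, gia)
  structure(list(time = time, g = g, vs = vs, omega = omega,
                 a_hat = gia - g, bias = bias, max_drift = max_drift,
                 params = params, dt = dt,
                 motion_window = protocol$motion_window),
            class = "svv_sim")
}

#' Signed roll-plane bias between the gravity estimate and the GIA
#'
#' The angle of the projection of `g` onto the y-z plane, measured from the
#' GIA direction, in degrees; positive toward +y (the tilt direction produced
#' by positive/counter-clockwise roll of the scene).
#'
#' @param g n x 3 matrix (or 3-vector) of gravity-estimate directions.
#' @param gia matching GIA directions.
#' @return Numeric vector of signed angles (degrees).
#' @export
signed_roll_bias <- function(g, gia) {
  g <- rbind(g); gia <- rbind(gia)
  atan2(g[, 2], g[, 3]) / DEG2RAD - atan2(gia[, 2], gia[, 3]) / DEG2RAD
}

#' Linearised asymptotic bias under constant roll rotation
#'
#' Small-angle steady state of the coupled system under constant scene
#' velocity: `theta_inf = t_s * velocity * K / (1 + K)` with
#' `K = go + ko * t_vs`. Useful as an analytic check on simulations in the
#' small-bias regime.
#'
#' @param params [model_params()] (attenuate first for noisy conditions).
#' @param velocity_deg_s Scene speed (deg/s).
#' @return Asymptotic bias (degrees).
#' @export
linearized_asymptote <- function(params, velocity_deg_s) {
  k <- params$go + params$ko * params$t_vs
  params$t_s * velocity_deg_s * k / (1 + k)
}

#' @exportS3Method base::print
print.svv_sim <- function(x, ...) {
  cat(sprintf("svv_sim: %d samples over %.1f s (dt = %.4g s)\n",
              length(x$time), max(x$time), x$dt))
  cat(sprintf("  final bias %.3f deg; max |G| drift %.2e\n",
              x$bias[length(x$bias)], x$max_drift))
  invisible(x)
}

#' Tidy a simulation result
#'
#' @param x An `svv_sim`.
#' @param ... Unused.
#' @return A tibble with columns `time_s`, `gx`, `gy`, `gz`, `omega_deg_s`
#'   (signed roll component) and `bias_deg`.
#' @export
as_tibble_sim <- function(x, ...) {
  stopifnot(inherits(x, "svv_sim"))
  tibble::tibble(time_s = x$time,
                 gx = x$g[, 1], gy = x$g[, 2], gz = x$g[, 3],
                 omega_deg_s = x$omega[, 1],
                 bias_deg = x$bias)
}

#' Write a simulation result to CSV
#'
#' @param x An `svv_sim`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(x, path) {
  utils::write.csv(as_tibble_sim(x), path, row.names = FALSE)
  invisible(path)
}
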