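#' Annulus display geometry
#'
#' @param inner_diameter,outer_diameter Annulus diameters (m).
#' @param dot_density Dots per square metre.
#' @param dot_diameter Dot diameter (m).
#' @param viewing_distance Observer-to-screen distance (m).
#' @return An object of class `svv_annulus`.
#' @export
annulus_spec <- function(inner_diameter = 0.48, outer_diameter = 2.44,
                         dot_density = 1460, dot_diameter = 0.012,
                         viewing_distance = 0.60) {
  if (!(inner_diameter > 0 && inner_diameter <= outer_diameter)) {
    stop("need 0 < inner_diameter <= outer_diameter", call. = FALSE)
  }
  if (dot_density < 0) stop("dot_density must be >= 0", call. = FALSE)
  structure(list(inner_diameter = inner_diameter,
                 outer_diameter = outer_diameter,
                 dot_density = dot_density,
                 dot_diameter = dot_diameter,
                 viewing_distance = viewing_distance),
            class = "svv_annulus")
}

#' Rotational noise specification for the dot field
#'
#' @param noise_fraction Noise proportion p in `[0, 0.8]`. Each dot's
#'   frame-to-frame jump vector is rotated by an independent angle uniform on
#'   `[-180p, +180p]` degrees.
#' @param field_velocity Desired net field angular velocity (deg/s, positive =
#'   counter-clockwise).
#' @param frame_rate Display frame rate (Hz).
#' @return An object of class `svv_noise`.
#' @export
noise_spec <- function(noise_fraction = 0, field_velocity = 16,
                       frame_rate = 60) {
  if (noise_fraction < 0 || noise_fraction > 0.8) {
    stop("noise_fraction must lie in [0, 0.8]", call. = FALSE)
  }
  if (frame_rate <= 0) stop("frame_rate must be > 0", call. = FALSE)
  structure(list(noise_fraction = noise_fraction,
                 field_velocity = field_velocity,
                 frame_rate = frame_rate),
            class = "svv_noise")
}

#' Velocity-preserving scale constant
#'
#' Rotating each dot's jump vector by an angle uniform on `[-180p, +180p]`
#' degrees shrinks the expected motion along the intended direction by
#' `E[cos theta] = sin(pi p) / (pi p)`. Scaling the jump magnitude by
#' `c = (pi p) / sin(pi p)` restores the net field velocity exactly. The
#' constant diverges as p approaches 1 (100% noise yields zero net motion).
#'
#' @param p Noise fraction in `[0, 1)`.
#' @return Scale constant (dimensionless, >= 1).
#' @export
scale_constant <- function(p) {
  if (any(p < 0 | p >= 1)) {
    stop("scale constant is defined for p in [0, 1): it diverges at 100% noise",
         call. = FALSE)
  }
  ifelse(p == 0, 1, (pi * p) / sin(pi * p))
}

#' Number of dots in the annulus
#'
#' @param annulus [annulus_spec()].
#' @return Integer count: `round(density * pi * (R_out^2 - R_in^2))`.
#' @export
n_dots <- function(annulus) {
  r_in <- annulus$inner_diameter / 2
  r_out <- annulus$outer_diameter / 2
  round(annulus$dot_density * pi * (r_out^2 - r_in^2))
}

#' Visual angle subtended by a frontal extent
#'
#' @param extent Physical extent (m), >= 0.
#' @param distance Viewing distance (m), > 0.
#' @return Visual angle in degrees: `2 * atan(extent / (2 * distance))`.
#' @export
visual_angle <- function(extent, distance) {
  if (any(extent < 0)) stop("extent must be >= 0", call. = FALSE)
  if (any(distance <= 0)) stop("distance must be > 0", call. = FALSE)
  2 * atan(extent / (2 * distance)) * 180 / pi
}

#' Initialise a random dot field
#'
#' Dots are placed uniformly over the annulus area (radius drawn as the
#' square root of a uniform variate between the squared radii).
#'
#' @param annulus [annulus_spec()].
#' @param n Number of dots; defaults to [n_dots()].
#' @return An object of class `svv_dot_field` with polar coordinates
#'   `r` (m) and `az` (rad).
#' @export
make_dot_field <- function(annulus, n = n_dots(annulus)) {
  r_in <- annulus$inner_diameter / 2
  r_out <- annulus$outer_diameter / 2
  r <- sqrt(stats::runif(n, r_in^2, r_out^2))
  az <- stats::runif(n, 0, 2 * pi)
  structure(list(r = r, az = az, annulus = annulus),
            class = "svv_dot_field")
}

#' Advance the dot field by one frame
#'
#' Each dot's nominal tangential jump (arc length `r * omega * dt`) is
#' rotated in the image plane by an independent angle uniform on
#' `[-180p, +180p]` degrees and scaled by the velocity-preserving constant
#' [scale_constant()], so that the expected net angular velocity of the field
#' equals the nominal velocity. Dots whose jump leaves the annulus are
#' respawned uniformly at random inside it (limited-lifetime style) and are
#' excluded from the realized-velocity bookkeeping for that frame.
#'
#' @param field [make_dot_field()].
#' @param noise [noise_spec()].
#' @param rescale Apply the velocity-preserving scale constant (default
#'   `TRUE`). With `rescale = FALSE` the raw rotated jumps are used; this
#'   also permits `noise_fraction = 1`, where net motion vanishes.
#' @return The advanced field, with attributes `daz` (realized signed
#'   azimuthal jump per dot, rad; `NA` for respawned dots) and `respawned`
#'   (logical).
#' @export
advance_frame <- function(field, noise, rescale = TRUE) {
  stopifnot(inherits(field, "svv_dot_field"), inherits(noise, "svv_noise"))
  p <- noise$noise_fraction
  if (!rescale && p > 1) stop("noise_fraction must be <= 1", call. = FALSE)
  annulus <- field$annulus
  r_in <- annulus$inner_diameter / 2
  r_out <- annulus$outer_diameter / 2
  dt <- 1 / noise$frame_rate
  omega_rad <- noise$field_velocity * pi / 180
  cc <- if (rescale) scale_constant(p) else 1

  n <- length(field$r)
  x <- field$r * cos(field$az)
  y <- field$r * sin(field$az)
  # nominal jump: the exact chord of the frame's rigid rotation, so that
  # zero noise reproduces rigid rotation to machine precision
  a <- omega_rad * dt
  jx <- x * (cos(a) - 1) - y * sin(a)
  jy <- x * sin(a) + y * (cos(a) - 1)
  phi <- stats::runif(n, -pi * p, pi * p)
  cphi <- cos(phi); sphi <- sin(phi)
  jx2 <- cc * (jx * cphi - jy * sphi)
  jy2 <- cc * (jx * sphi + jy * cphi)
  xn <- x + jx2
  yn <- y + jy2
  rn <- sqrt(xn^2 + yn^2)
  azn <- atan2(yn, xn)

  out <- rn < r_in | rn > r_out
  daz <- atan2(sin(azn - field$az), cos(azn - field$az))
  if (any(out)) {
    k <- sum(out)
    rn[out] <- sqrt(stats::runif(k, r_in^2, r_out^2))
    azn[out] <- stats::runif(k, 0, 2 * pi)
    daz[out] <- NA_real_
  }
  new_field <- structure(list(r = rn, az = azn, annulus = annulus),
                         class = "svv_dot_field")
  attr(new_field, "daz") <- daz
  attr(new_field, "respawned") <- out
  new_field
}

#' Empirical net field velocity over repeated frames
#'
#' Advances a dot field for `n_frames` frames and returns the mean and
#' standard error of the realized per-dot angular velocity, for checking
#' that the noise algorithm preserves the nominal field velocity.
#'
#' @param noise [noise_spec()].
#' @param annulus [annulus_spec()].
#' @param n_frames Number of frames to advance.
#' @param n_dots Number of dots to track (defaults to the full field).
#' @param rescale Passed to [advance_frame()].
#' @return A list with `mean_deg_s`, `se_deg_s`, `n` (dot-frames used).
#' @export
measure_field_velocity <- function(noise, annulus = annulus_spec(),
                                   n_frames = 100, n_dots = NULL,
                                   rescale = TRUE) {
  field <- if (is.null(n_dots)) make_dot_field(annulus) else
    make_dot_field(annulus, n = n_dots)
  dt <- 1 / noise$frame_rate
  sum_d <- 0; sum_d2 <- 0; n_used <- 0
  for (f in seq_len(n_frames)) {
    field <- advance_frame(field, noise, rescale = rescale)
    d <- attr(field, "daz")
    d <- d[!is.na(d)] / dt * 180 / pi
    sum_d <- sum_d + sum(d)
    sum_d2 <- sum_d2 + sum(d^2)
    n_used <- n_used + length(d)
  }
  m <- sum_d / n_used
  v <- max(0, (sum_d2 - n_used * m^2) / (n_used - 1))
  list(mean_deg_s = m, se_deg_s = sqrt(v / n_used), n = n_used)
}

#' Tidy a dot field
#'
#' @param field [make_dot_field()].
#' @param frame Frame index to record in the output.
#' @return Tibble with columns `frame`, `dot_id`, `x_m`, `y_m`.
#' @export
dot_field_positions <- function(field, frame = 0L) {
  tibble::tibble(frame = frame,
                 dot_id = seq_along(field$r),
                 x_m = field$r * cos(field$az),
                 y_m = field$r * sin(field$az))
}

#' Bar-position noise specification
#'
#' Low-frequency noise added to the angular position of the vertical-
#' indicator bar, compelling continuous correction by the participant.
#'
#' @param bandwidth Passband (Hz), length-2.
#' @param target_sd Target standard deviation (degrees).
#' @param range_limit Hard clip limit (degrees).
#' @param sample_rate Sample rate (Hz).
#' @return An object of class `svv_bar_noise`.
#' @export
bar_noise_spec <- function(bandwidth = c(0, 0.2), target_sd = 9.6,
                           range_limit = 35.9, sample_rate = 30) {
  stopifnot(length(bandwidth) == 2L, bandwidth[2] > bandwidth[1])
  if (target_sd <= 0) stop("target_sd must be > 0", call. = FALSE)
  if (range_limit <= target_sd) {
    stop("range_limit must exceed target_sd", call. = FALSE)
  }
  structure(list(bandwidth = bandwidth, target_sd = target_sd,
                 range_limit = range_limit, sample_rate = sample_rate),
            class = "svv_bar_noise")
}

#' Generate a band-limited bar-noise trace
#'
#' White Gaussian noise is restricted to the passband by zeroing
#' out-of-band Fourier coefficients (an ideal zero-phase filter), centred,
#' rescaled to the target standard deviation, and clipped to the range
#' limit. The DC bin is always removed so the trace has zero mean.
#'
#' @param spec [bar_noise_spec()].
#' @param duration_s Trace duration (s), > 0.
#' @return Numeric vector of angles (degrees), length
#'   `round(duration_s * sample_rate)`.
#' @export
generate_bar_noise <- function(spec = bar_noise_spec(), duration_s = 50) {
  stopifnot(inherits(spec, "svv_bar_noise"))
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  n <- round(duration_s * spec$sample_rate)
  z <- stats::rnorm(n)
  zf <- stats::fft(z)
  freq <- seq(0, n - 1) / n * spec$sample_rate
  freq <- pmin(freq, spec$sample_rate - freq)  # two-sided spectrum
  keep <- freq >= spec$bandwidth[1] & freq <= spec$bandwidth[2]
  keep[1] <- FALSE  # drop DC: zero mean
  zf[!keep] <- 0
  x <- Re(stats::fft(zf, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x * spec$target_sd / s
  pmin(pmax(x, -spec$range_limit), spec$range_limit)
}
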