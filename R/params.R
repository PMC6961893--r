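#' Parameters of the visuo-vestibular state estimator
#'
#' Container for the gains and time constants of the velocity-storage /
#' somatogravic internal model. Defaults are the published estimates for a
#' seated, head-fixed observer viewing roll-plane visual rotation.
#'
#' @param ko Retinal-slip storage gain (1/s). The rate at which retinal slip
#'   charges the velocity-storage integrator.
#' @param kv Vestibular storage gain (1/s).
#' @param go Direct visual pathway gain (dimensionless).
#' @param gv Direct vestibular pathway gain (dimensionless).
#' @param kf Rotation-feedback gain on the GIA x G cross product feeding the
#'   storage integrator (default 0: the pathway is present but inactive).
#' @param t_vs Velocity-storage leak time constant (s), must be positive.
#' @param t_s Somatogravic time constant (s), must be positive. Governs how
#'   fast the internal gravity estimate is pulled back toward the
#'   gravito-inertial acceleration (GIA) signal.
#'
#' @return An object of class `svv_params` (a named list).
#' @examples
#' p <- model_params()
#' p$ko
#' apply_noise_attenuation(p, 0.5)$ko
#' @export
model_params <- function(ko = 0.11, kv = 0.2, go = 0.16, gv = 0.43,
                         kf = 0.0, t_vs = 15, t_s = 0.74) {
  p <- list(ko = ko, kv = kv, go = go, gv = gv, kf = kf,
            t_vs = t_vs, t_s = t_s)
  validate_params(p)
  structure(p, class = "svv_params")
}

validate_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("all model parameters must be finite scalars: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  if (p$t_vs <= 0) stop("t_vs must be > 0", call. = FALSE)
  if (p$t_s <= 0) stop("t_s must be > 0", call. = FALSE)
  for (nm in c("ko", "kv", "go", "gv", "kf")) {
    if (p[[nm]] < 0) stop(nm, " must be >= 0", call. = FALSE)
  }
  invisible(p)
}

#' @exportS3Method base::print
print.svv_params <- function(x, ...) {
  cat("Visuo-vestibular model parameters:\n")
  cat(sprintf("  ko = %g (1/s)   kv = %g (1/s)\n", x$ko, x$kv))
  cat(sprintf("  go = %g         gv = %g\n", x$go, x$gv))
  cat(sprintf("  kf = %g         t_vs = %g s   t_s = %g s\n",
              x$kf, x$t_vs, x$t_s))
  invisible(x)
}

#' Attenuate visual gains for a given stimulus noise fraction
#'
#' Visual noise reduces the weight of the visual cue. Following the
#' variance-weighting account, the two visual gains (`ko`, `go`) are
#' multiplied by `1 - noise_fraction`; vestibular gains and time constants are
#' untouched.
#'
#' @param params An [model_params()] object.
#' @param noise_fraction Proportion of stimulus noise, in `[0, 1)`.
#' @return A new `svv_params` object with attenuated visual gains.
#' @export
apply_noise_attenuation <- function(params, noise_fraction) {
  stopifnot(inherits(params, "svv_params"))
  if (!is.numeric(noise_fraction) || length(noise_fraction) != 1L ||
      !is.finite(noise_fraction) || noise_fraction < 0 || noise_fraction >= 1) {
    stop("noise_fraction must be a single value in [0, 1)", call. = FALSE)
  }
  params$ko <- params$ko * (1 - noise_fraction)
  params$go <- params$go * (1 - noise_fraction)
  params
}
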