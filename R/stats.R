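#' Fit the random-intercept mixed model for window-mean bias
#'
#' Maximum-likelihood fit (ML, not REML, so likelihood-ratio comparisons of
#' fixed effects are valid) of
#' `bias ~ <terms> + (1 | subject)` where the fixed terms are any subset of
#' velocity (numeric, deg/s), noise (numeric fraction) and their
#' interaction. With `terms = character(0)` the model is intercept-only.
#'
#' @param data Data frame with columns `subject`, `velocity`, `noise`, and
#'   the response named by `response` (default `window_mean_deg`, the
#'   per-subject-per-condition 27-40 s mean).
#' @param terms Character subset of `c("velocity", "noise", "interaction")`.
#' @param response Response column name.
#' @return An object of class `svv_lmm`: list with the `lme4` fit, `terms`,
#'   `logLik`, `n_par`, `fixef`, variance components.
#' @export
fit_bias_lmm <- function(data, terms = c("velocity", "noise", "interaction"),
                         response = "window_mean_deg") {
  if (length(terms) > 0) {
    terms <- unique(match.arg(terms, several.ok = TRUE))
  } else {
    terms <- character(0)
  }
  if (length(unique(data$subject)) < 2) {
    stop("need >= 2 subjects", call. = FALSE)
  }
  if (nrow(unique(data[, c("velocity", "noise")])) < 2) {
    stop("need >= 2 conditions", call. = FALSE)
  }
  if ("interaction" %in% terms &&
      !all(c("velocity", "noise") %in% terms)) {
    terms <- union(c("velocity", "noise"), terms)  # hierarchical interaction
  }
  rhs <- c("1",
           if ("velocity" %in% terms) "velocity",
           if ("noise" %in% terms) "noise",
           if ("interaction" %in% terms) "velocity:noise",
           "(1 | subject)")
  f <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  fit <- lme4::lmer(f, data = data, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fit = fit, terms = terms, formula = f,
                 logLik = as.numeric(stats::logLik(fit)),
                 n_par = attr(stats::logLik(fit), "df"),
                 fixef = lme4::fixef(fit),
                 subject_var = vc$vcov[vc$grp == "subject"][1],
                 resid_var = vc$vcov[vc$grp == "Residual"][1],
                 n_obs = stats::nobs(fit)),
            class = "svv_lmm")
}

#' @exportS3Method base::print
print.svv_lmm <- function(x, ...) {
  cat("Random-intercept mixed model (ML):",
      deparse(x$formula), "\n")
  cat(sprintf("  logLik %.3f, %d parameters, %d obs\n",
              x$logLik, x$n_par, x$n_obs))
  print(round(x$fixef, 4))
  invisible(x)
}

#' Likelihood-ratio test between nested mixed models
#'
#' @param nested,full `svv_lmm` fits of the same data; `nested`'s fixed
#'   terms must be a subset of `full`'s.
#' @return An object of class `svv_lrt`: list with `chisq`, `df`, `p`.
#' @export
lrt <- function(nested, full) {
  stopifnot(inherits(nested, "svv_lmm"), inherits(full, "svv_lmm"))
  if (!all(nested$terms %in% full$terms)) {
    stop("models are not nested (fixed terms are not a subset)",
         call. = FALSE)
  }
  if (nested$n_obs != full$n_obs) {
    stop("models were not fitted to the same data", call. = FALSE)
  }
  df <- full$n_par - nested$n_par
  if (identical(sort(nested$terms), sort(full$terms))) df <- 0L
  chisq <- max(0, 2 * (full$logLik - nested$logLik))
  p <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else 1
  structure(list(chisq = chisq, df = df, p = p), class = "svv_lrt")
}

#' @exportS3Method base::print
print.svv_lrt <- function(x, ...) {
  cat(sprintf("LRT: chisq = %.3f, df = %d, p = %.3g\n", x$chisq, x$df, x$p))
  invisible(x)
}

#' Likelihood-ratio model-comparison table for the bias data
#'
#' Runs the standard ladder of comparisons (noise, velocity, both, and the
#' interaction against the intercept-only and full models).
#'
#' @param data As in [fit_bias_lmm()].
#' @param response Response column name.
#' @return Tibble with columns `comparison`, `chisq`, `df`, `p`.
#' @export
lrt_table <- function(data, response = "window_mean_deg") {
  m0 <- fit_bias_lmm(data, character(0), response)
  mn <- fit_bias_lmm(data, "noise", response)
  mv <- fit_bias_lmm(data, "velocity", response)
  mvn <- fit_bias_lmm(data, c("velocity", "noise"), response)
  mfull <- fit_bias_lmm(data, c("velocity", "noise", "interaction"),
                        response)
  rows <- list(
    c("noise vs intercept-only", lrt(m0, mn)),
    c("velocity vs intercept-only", lrt(m0, mv)),
    c("velocity + noise vs intercept-only", lrt(m0, mvn)),
    c("velocity * noise vs intercept-only", lrt(m0, mfull)),
    c("interaction added to velocity + noise", lrt(mvn, mfull)))
  tibble::tibble(
    comparison = vapply(rows, `[[`, character(1), 1),
    chisq = vapply(rows, function(r) r[[2]], numeric(1)),
    df = vapply(rows, function(r) r[[3]], numeric(1)),
    p = vapply(rows, function(r) r[[4]], numeric(1)))
}

#' Slope of the point of subjective equality on noise
#'
#' Fits `pse ~ noise` with a per-subject random slope for noise
#' (`(0 + noise | subject)`) by maximum likelihood, and tests the fixed
#' slope with a t statistic on `n_subjects - 1` degrees of freedom (a
#' deliberate simple approximation in place of Satterthwaite machinery).
#' With a single subject, or when the random-slope fit is degenerate, an
#' ordinary least-squares fit is used instead.
#'
#' @param pse_table Data frame with columns `subject`, `noise`, `pse`
#'   (deg/s); rows with missing `pse` are dropped.
#' @return List with `slope`, `se`, `t`, `df`, `p`, `method`.
#' @export
fit_pse_slope <- function(pse_table) {
  d <- pse_table[!is.na(pse_table$pse), , drop = FALSE]
  if (length(unique(d$noise)) < 2) {
    stop("need >= 2 noise levels", call. = FALSE)
  }
  n_subj <- length(unique(d$subject))
  use_lm <- n_subj < 2
  fit <- NULL
  if (!use_lm) {
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(pse ~ noise + (0 + noise | subject), data = d,
                   REML = FALSE))),
      error = function(e) NULL)
    if (is.null(fit)) use_lm <- TRUE
  }
  if (use_lm) {
    lmfit <- stats::lm(pse ~ noise, data = d)
    # a perfect line is legitimate input here (degenerate but defined)
    sm <- suppressWarnings(summary(lmfit))$coefficients
    slope <- sm["noise", "Estimate"]
    se <- sm["noise", "Std. Error"]
    df <- stats::df.residual(lmfit)
    method <- "ols"
  } else {
    sm <- summary(fit)$coefficients
    slope <- sm["noise", "Estimate"]
    se <- sm["noise", "Std. Error"]
    df <- max(1, n_subj - 1)
    method <- "lmm-random-slope"
  }
  tval <- if (se > 0) slope / se else if (slope == 0) 0 else Inf
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(slope = unname(slope), se = unname(se), t = unname(tval),
       df = df, p = unname(p), method = method)
}
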