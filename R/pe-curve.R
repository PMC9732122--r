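#' @name pe_curve
#' @title Photosynthesis/ETR-irradiance (P-E) response curves
#'
#' @description
#' The package models light-response curves with the Eilers-Peeters
#' rational function
#' \deqn{P(E) = \frac{E}{aE^2 + bE + c}}
#' which yields the standard descriptors
#' \deqn{P_{max} = \frac{1}{b + 2\sqrt{ac}}, \quad
#'       \alpha = \frac{1}{c}, \quad
#'       E_{opt} = \sqrt{c/a}, \quad
#'       E_K = P_{max}/\alpha.}
#' `alpha` is the light-limited initial slope, `Pmax` the maximum response,
#' `Eopt` the optimum irradiance (infinite when there is no photoinhibition,
#' i.e. `a = 0`), and `Ek` the light-saturation parameter.
NULL

eilers_abc <- function(alpha, Pmax, Eopt) {
  cc <- 1 / alpha
  a <- if (is.finite(Eopt)) cc / Eopt^2 else 0
  b <- 1 / Pmax - 2 * sqrt(a * cc)
  c(a = a, b = b, c = cc)
}

eilers_descriptors <- function(a, b, c) {
  alpha <- 1 / c
  Pmax <- 1 / (b + 2 * sqrt(a * c))
  Eopt <- if (a > 0) sqrt(c / a) else Inf
  list(alpha = alpha, Pmax = Pmax, Eopt = Eopt, Ek = Pmax / alpha)
}

eilers_eval <- function(E, a, b, c) {
  ifelse(E == 0, 0, E / (a * E^2 + b * E + c))
}

#' Construct a P-E curve from its physiological descriptors
#'
#' Builds a `pe_fit` object directly from (`alpha`, `Pmax`, `Eopt`) rather
#' than from data; used for synthetic ground truth and for closed-form
#' checks.
#'
#' @param alpha Initial slope (response units per umol quanta m^-2 s^-1).
#' @param Pmax Maximum response.
#' @param Eopt Optimum irradiance; `Inf` for no photoinhibition.
#' @return A `pe_fit` object (without residual information).
#' @export
pe_curve <- function(alpha, Pmax, Eopt = Inf) {
  assert_num(alpha, "alpha", lower = 0, strict_lower = TRUE)
  assert_num(Pmax, "Pmax", lower = 0, strict_lower = TRUE)
  if (is.finite(Eopt)) assert_num(Eopt, "Eopt", lower = 0, strict_lower = TRUE)
  p <- eilers_abc(alpha, Pmax, Eopt)
  if (p[["b"]] < 0 && p[["b"]]^2 >= 4 * p[["a"]] * p[["c"]]) {
    dzd_stop("config_error",
             "inconsistent descriptors: requires Eopt < 4 Ek (got Eopt=%g, Ek=%g)",
             Eopt, Pmax / alpha)
  }
  new_pe_fit(p[["a"]], p[["b"]], p[["c"]], residual_norm = NA_real_,
             points = NULL)
}

new_pe_fit <- function(a, b, c, residual_norm, points) {
  d <- eilers_descriptors(a, b, c)
  structure(list(a = a, b = b, c = c,
                 alpha = d$alpha, Pmax = d$Pmax, Eopt = d$Eopt, Ek = d$Ek,
                 residual_norm = residual_norm, points = points),
            class = "pe_fit")
}

#' Evaluate a fitted P-E curve
#'
#' @param object A `pe_fit`.
#' @param E Irradiance(s) at which to evaluate (>= 0). Supply as `E = ...`.
#' @param ... Unused.
#' @return Response value(s).
#' @export
predict.pe_fit <- function(object, E, ...) {
  assert_num(E, "E", lower = 0, len = NULL)
  eilers_eval(E, object$a, object$b, object$c)
}

#' @export
print.pe_fit <- function(x, ...) {
  cat(sprintf(
    "Eilers-Peeters P-E fit: alpha=%.6g  Pmax=%.6g  Ek=%.6g  Eopt=%s%s\n",
    x$alpha, x$Pmax, x$Ek,
    if (is.finite(x$Eopt)) sprintf("%.6g", x$Eopt) else "Inf (no photoinhibition)",
    if (is.na(x$residual_norm)) "" else sprintf("  |r|=%.3g", x$residual_norm)))
  invisible(x)
}

#' Fit an Eilers-Peeters P-E curve to (irradiance, response) points
#'
#' Nonlinear least squares on the rational parameters (a, b, c) via
#' Levenberg-Marquardt, with `a` bounded below by zero so curves without
#' photoinhibition are admissible (then `Eopt = Inf`). Starting values:
#' `alpha0` from the slope of the two lowest-irradiance points with a
#' positive response, `Pmax0` from the maximum response and `Eopt0` from its
#' irradiance. The fit is invariant to point ordering.
#'
#' @param E Irradiances (umol quanta m^-2 s^-1), or a two-column
#'   data frame `(E, response)`.
#' @param response Responses (>= 0), same length as `E`.
#' @param max_iter Iteration cap for the optimizer.
#' @return A `pe_fit` with descriptors `alpha`, `Pmax`, `Ek = Pmax/alpha`,
#'   `Eopt` and the residual norm.
#' @export
fit_pe_curve <- function(E, response = NULL, max_iter = 500L) {
  if (is.data.frame(E)) {
    response <- E[[2L]]
    E <- E[[1L]]
  }
  if (length(E) != length(response) || anyNA(E) || anyNA(response)) {
    dzd_stop("insufficient_data", "E and response must be equal-length, NA-free")
  }
  if (any(response < 0) || any(E < 0)) {
    dzd_stop("insufficient_data", "E and response must be non-negative")
  }
  keep <- order(E)
  E <- E[keep]; response <- response[keep]
  if (length(unique(E)) < 4L || all(response == 0)) {
    dzd_stop("insufficient_data",
             ">= 4 distinct irradiances with a non-zero response are required")
  }

  pos <- which(response > 0)
  lowest <- utils::head(pos[order(E[pos])], 2L)
  alpha0 <- if (length(lowest) == 2L && diff(E[lowest]) > 0) {
    diff(response[lowest]) / diff(E[lowest])
  } else {
    response[pos[1L]] / E[pos[1L]]
  }
  if (!is.finite(alpha0) || alpha0 <= 0) alpha0 <- max(response) / max(E)
  Pmax0 <- max(response)
  Eopt0 <- E[which.max(response)]
  c0 <- 1 / alpha0
  a0 <- 1 / (Eopt0^2 * Pmax0)
  b0 <- max(1 / Pmax0 - 2 * sqrt(a0 * c0), 1e-8)

  resid_fn <- function(par) {
    den <- par[1L] * E^2 + par[2L] * E + par[3L]
    pred <- ifelse(E == 0, 0, E / den)
    bad <- den <= 0 & E > 0
    pred[bad] <- 1e6 * max(response)
    pred - response
  }
  fit <- minpack.lm::nls.lm(
    par = c(a0, b0, c0), fn = resid_fn,
    lower = c(0, -Inf, 1e-12),
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-15, ptol = 1e-15, gtol = 0))
  if (!fit$info %in% 1:4) {
    dzd_stop("fit_failure",
             "P-E fit did not converge (info=%d: %s)", fit$info, fit$message,
             data = fit)
  }
  par <- fit$par
  new_pe_fit(par[1L], par[2L], par[3L],
             residual_norm = sqrt(sum(fit$fvec^2)),
             points = data.frame(E = E, response = response))
}

#' Integrate a P-E response over one phase of the diel light cycle
#'
#' Evaluates the fitted response along the half-sine light schedule and
#' accumulates it with a composite trapezoid over the chosen phase,
#' producing the phase-integrated amounts reported per 12 h. A light-driven
#' response integrates to exactly zero over the dark phase.
#'
#' @param fit A `pe_fit`.
#' @param profile A [diel_light_profile()].
#' @param phase `"light"` or `"dark"`.
#' @param dt Integration step in hours (must be <= 0.25).
#' @return The phase integral (response units x h per phase).
#' @export
integrate_diel <- function(fit, profile, phase = c("light", "dark"),
                           dt = 0.05) {
  phase <- match.arg(phase)
  stopifnot(inherits(fit, "pe_fit"), inherits(profile, "diel_light_profile"))
  if (dt <= 0 || dt > 0.25) {
    dzd_stop("config_error", "integration step dt must be in (0, 0.25] h")
  }
  bounds <- if (phase == "light") c(0, profile$photoperiod) else
    c(profile$photoperiod, profile$cycle_length)
  t <- seq(bounds[1L], bounds[2L], by = dt)
  if (t[length(t)] < bounds[2L]) t <- c(t, bounds[2L])
  tt <- pmin(t, profile$cycle_length * (1 - 1e-12))
  y <- predict(fit, E = irradiance_at(tt, profile))
  trapz_int(t, y)
}
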