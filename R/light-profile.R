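#' Diel light profile
#'
#' Describes the sinusoidal light:dark cycle delivered by the
#' photobioreactor: irradiance follows a half-sine over the photoperiod
#' (peaking mid-light) and is zero throughout the dark phase. Hours are
#' counted from light onset, so the light phase is `[0, photoperiod)` and
#' the dark phase `[photoperiod, cycle_length)`.
#'
#' @param E_max Maximum irradiance at the middle of the light period
#'   (umol photons m^-2 s^-1).
#' @param photoperiod Length of the light phase in hours (default 12).
#' @param cycle_length Full cycle length in hours (fixed at 24).
#' @return An object of class `diel_light_profile`.
#' @examples
#' prof <- diel_light_profile(400)
#' irradiance_at(6, prof)   # mid-light peak: 400
#' irradiance_at(18, prof)  # dark: 0
#' @export
diel_light_profile <- function(E_max, photoperiod = 12, cycle_length = 24) {
  assert_num(E_max, "E_max", lower = 0, strict_lower = TRUE)
  assert_num(photoperiod, "photoperiod", lower = 0, strict_lower = TRUE)
  if (cycle_length != 24) {
    dzd_stop("config_error", "cycle_length is fixed at 24 h")
  }
  if (photoperiod >= cycle_length) {
    dzd_stop("config_error", "photoperiod must be < cycle_length")
  }
  structure(list(E_max = E_max, photoperiod = photoperiod,
                 cycle_length = cycle_length),
            class = "diel_light_profile")
}

#' Irradiance at a given hour of the diel cycle
#'
#' Half-sine light schedule: `E_max * sin(pi * t / photoperiod)` for
#' `t` within the photoperiod, zero in the dark. Continuous at both phase
#' boundaries.
#'
#' @param t Hour(s) since light onset, each in `[0, 24)`. Vectorized.
#' @param profile A [diel_light_profile()].
#' @return Irradiance(s), umol photons m^-2 s^-1.
#' @export
irradiance_at <- function(t, profile) {
  stopifnot(inherits(profile, "diel_light_profile"))
  if (!is.numeric(t) || anyNA(t) ||
      any(t < 0) || any(t >= profile$cycle_length)) {
    dzd_stop("domain_error", "t must lie in [0, %g)", profile$cycle_length)
  }
  E <- ifelse(t <= profile$photoperiod,
              profile$E_max * sin(pi * t / profile$photoperiod), 0)
  pmax(E, 0)
}

#' @export
print.diel_light_profile <- function(x, ...) {
  cat(sprintf("Diel light profile: %g:%g h L:D half-sine, E_max %g umol photons m-2 s-1\n",
              x$photoperiod, x$cycle_length - x$photoperiod, x$E_max))
  invisible(x)
}
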