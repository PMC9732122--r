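#' ETR calculation context
#'
#' Physical constants for converting fluorescence yields into absolute,
#' chlorophyll-normalized electron transport rates with the "absorption"
#' method.
#'
#' @param KA Instrument-specific calibration factor (m^-1, default 11800).
#' @param chl Chlorophyll a concentration (mg m^-3).
#' @param invert_time_factor The published formula carries a factor
#'   `1/3600` described as a seconds-to-hours conversion, although a
#'   strict unit audit of `E * KA / chl` (per second) would multiply by
#'   3600 to obtain hourly rates. The default `FALSE` evaluates the
#'   formula exactly as printed (divide); set `TRUE` to multiply instead.
#' @return An `etr_context` object.
#' @export
etr_context <- function(KA = 11800, chl, invert_time_factor = FALSE) {
  assert_num(KA, "KA", lower = 0, strict_lower = TRUE)
  assert_num(chl, "chl", lower = 0, strict_lower = TRUE)
  structure(list(KA = KA, chl = chl, seconds_per_hour = 3600,
                 invert_time_factor = isTRUE(invert_time_factor)),
            class = "etr_context")
}

time_factor <- function(ctx) {
  if (ctx$invert_time_factor) ctx$seconds_per_hour else 1 / ctx$seconds_per_hour
}

#' A single FRRf fluorescence yield set
#'
#' One fast repetition rate fluorometry induction measurement: the
#' dark-regulated minimum and maximum yields (`F0`, `Fm`) and the
#' steady-state and light-saturated maximal yields (`Fp` = F',
#' `Fmp` = Fm') recorded at actinic irradiance `E`. Yields are relative
#' fluorescence (dimensionless); only their ratios enter the ETR formula.
#'
#' @param F0,Fm Dark minimum and maximum yields (`Fm > F0 > 0`).
#' @param Fp,Fmp Light steady-state and maximal yields (`Fmp >= Fp > 0`).
#' @param E Actinic irradiance (umol photons m^-2 s^-1, >= 0).
#' @return A `frrf_yields` object.
#' @export
frrf_yields <- function(F0, Fm, Fp, Fmp, E) {
  assert_num(F0, "F0", lower = 0, strict_lower = TRUE)
  assert_num(Fm, "Fm", lower = 0, strict_lower = TRUE)
  assert_num(Fp, "Fp", lower = 0, strict_lower = TRUE)
  assert_num(Fmp, "Fmp", lower = 0, strict_lower = TRUE)
  assert_num(E, "E", lower = 0)
  if (Fm <= F0) dzd_stop("degenerate_yields", "Fm must exceed F0")
  if (Fp > Fmp) dzd_stop("invalid_measurement", "F' exceeds Fm'")
  structure(list(F0 = F0, Fm = Fm, Fp = Fp, Fmp = Fmp, E = E),
            class = "frrf_yields")
}

#' Absolute Chl-normalized ETR from fluorescence yields
#'
#' Implements the "absorption" method:
#' \deqn{ETR = \frac{F_m F_0}{F_m - F_0} \cdot
#'             \frac{F_m' - F'}{F_m'} \cdot E \cdot
#'             \frac{K_A}{[Chl\,a]} \cdot \frac{1}{3600}}
#' in umol e- (ug Chl a)^-1 h^-1. The first factor rescales the
#' photochemical yield by the dark-acclimated PSII capacity; the second is
#' the operating photochemical efficiency at irradiance `E`.
#'
#' @param y A [frrf_yields()] object, or a data frame with columns
#'   `F0, Fm, Fp, Fmp, E` (one measurement per row, vectorized).
#' @param ctx An [etr_context()].
#' @return Numeric rate(s), non-negative.
#' @export
etr_from_yields <- function(y, ctx) {
  stopifnot(inherits(ctx, "etr_context"))
  if (inherits(y, "frrf_yields")) y <- as.data.frame(unclass(y))
  need <- c("F0", "Fm", "Fp", "Fmp", "E")
  if (!all(need %in% names(y))) {
    dzd_stop("parse_error", "yield table must have columns %s",
             paste(need, collapse = ", "))
  }
  if (any(y$Fm <= y$F0)) {
    dzd_stop("degenerate_yields", "Fm must exceed F0 in every yield set")
  }
  if (any(y$Fp > y$Fmp)) {
    dzd_stop("invalid_measurement", "F' exceeds Fm' in a yield set")
  }
  (y$Fm * y$F0 / (y$Fm - y$F0)) * ((y$Fmp - y$Fp) / y$Fmp) *
    y$E * ctx$KA / ctx$chl * time_factor(ctx)
}

#' Fit the ETR-irradiance response of one FRRf ladder
#'
#' Converts each yield set of a P-E ladder to an absolute ETR and fits the
#' Eilers-Peeters curve, yielding `ETRmax` (= `Pmax`), `alpha^ETR` and
#' `Ek`.
#'
#' @param ladder Data frame with columns `E, F0, Fm, Fp, Fmp`.
#' @param ctx An [etr_context()].
#' @return A `pe_fit`.
#' @export
fit_etr_ladder <- function(ladder, ctx) {
  etr <- etr_from_yields(ladder, ctx)
  fit_pe_curve(ladder$E, etr)
}

#' Read an FRRf ladder CSV (`E,F0,Fm,Fp,Fmp`)
#' @param path File path.
#' @return Data frame.
#' @export
read_frrf <- function(path) {
  read_dzd_csv(path, c("E", "F0", "Fm", "Fp", "Fmp"))
}

#' Write fitted P-E parameters for several stages/timepoints
#'
#' @param fits Named list of `pe_fit` objects; names are used as the
#'   `stage` column (e.g. `"ETR_1"`, `"C14"`).
#' @param path Output CSV path (`stage,t_h,alpha,Pmax,Ek,Eopt,residual`).
#' @param t_h Optional numeric vector of sampling hours (NA where not
#'   applicable).
#' @export
write_pe_fit <- function(fits, path, t_h = rep(NA_real_, length(fits))) {
  df <- data.frame(
    stage = names(fits),
    t_h = t_h,
    alpha = vapply(fits, `[[`, numeric(1), "alpha"),
    Pmax = vapply(fits, `[[`, numeric(1), "Pmax"),
    Ek = vapply(fits, `[[`, numeric(1), "Ek"),
    Eopt = vapply(fits, `[[`, numeric(1), "Eopt"),
    residual = vapply(fits, `[[`, numeric(1), "residual_norm"))
  write_dzd_csv(df, path)
}
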