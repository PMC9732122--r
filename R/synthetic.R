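#' Ground truth for a synthetic diel dataset
#'
#' Bundles every generating parameter of one synthetic photobioreactor
#' run so that pipeline output can be checked against known truth: the
#' true ETR and carbon P-E curves, the O2-electrode respiration magnitudes
#' per phase, the diel gross-O2 capacity schedule, the nocturnal
#' N2-fixation schedule, the dark-acclimated PSII yield `fvfm`, the Chl a
#' concentration, the OD735 carbon-pool calibration, the measurement noise
#' CV and the RNG seed.
#'
#' @param species Species label.
#' @param pe_etr,pe_c True ETR and carbon [pe_curve()]s (hourly units).
#' @param resp_light,resp_dark Respiratory O2 consumption magnitudes in
#'   the light/dark phase (umol O2 (ug Chl)^-1 h^-1, >= 0).
#' @param gross_o2_schedule Data frame `t_h, value`: gross O2 evolution
#'   capacity (umol O2 (ug Chl)^-1 h^-1) at the electrode sampling hours.
#' @param n2fix_schedule Data frame `t_h, value`: N2 fixation rate
#'   (nmol N2 (ug Chl)^-1 h^-1) per sampling hour; non-zero entries must
#'   fall in the dark phase.
#' @param fvfm Dark-acclimated PSII photochemical yield, in (0, 1).
#' @param chl Chl a concentration (mg m^-3, > 0).
#' @param od_params List `t_peak, t_ref, fold_ref, fold_end` calibrating
#'   the OD735 carbon-pool proxy: the normalized series peaks at hour
#'   `t_peak`, passes `fold_ref` at hour `t_ref` and ends the dark phase
#'   at `fold_end`.
#' @param noise_cv Coefficient of variation of multiplicative Gaussian
#'   measurement noise applied to every instrument readout (>= 0).
#' @param seed Integer master seed; fixes the dataset bit-for-bit.
#' @param photoperiod Light-phase length (h).
#' @return A `synthetic_truth` object.
#' @export
synthetic_truth <- function(species, pe_etr, pe_c, resp_light, resp_dark,
                            gross_o2_schedule, n2fix_schedule, fvfm, chl,
                            od_params, noise_cv = 0, seed = 1L,
                            photoperiod = 12) {
  stopifnot(inherits(pe_etr, "pe_fit"), inherits(pe_c, "pe_fit"))
  assert_num(resp_light, "resp_light", lower = 0)
  assert_num(resp_dark, "resp_dark", lower = 0)
  assert_num(fvfm, "fvfm", lower = 0, upper = 1, strict_lower = TRUE)
  if (fvfm >= 1) dzd_stop("config_error", "fvfm must be < 1")
  assert_num(chl, "chl", lower = 0, strict_lower = TRUE)
  if (noise_cv < 0) dzd_stop("config_error", "noise_cv must be >= 0")
  assert_num(as.numeric(seed), "seed")
  for (nm in c("t_peak", "t_ref", "fold_ref", "fold_end")) {
    if (is.null(od_params[[nm]])) {
      dzd_stop("config_error", "od_params must contain '%s'", nm)
    }
  }
  chk_sched <- function(s, name) {
    if (!is.data.frame(s) || !all(c("t_h", "value") %in% names(s))) {
      dzd_stop("config_error", "%s must be a data frame (t_h, value)", name)
    }
    if (any(s$value < 0)) dzd_stop("config_error", "%s rates must be >= 0", name)
    s
  }
  chk_sched(gross_o2_schedule, "gross_o2_schedule")
  chk_sched(n2fix_schedule, "n2fix_schedule")
  if (any(n2fix_schedule$value > 0 & n2fix_schedule$t_h < photoperiod)) {
    dzd_stop("config_error",
             "n2fix_schedule must be zero during the light phase")
  }
  structure(list(species = species, pe_etr = pe_etr, pe_c = pe_c,
                 resp_light = resp_light, resp_dark = resp_dark,
                 gross_o2_schedule = gross_o2_schedule,
                 n2fix_schedule = n2fix_schedule,
                 fvfm = fvfm, chl = chl, od_params = od_params,
                 noise_cv = noise_cv, seed = as.integer(seed),
                 photoperiod = photoperiod),
            class = "synthetic_truth")
}

# Solve the ETR initial slope so the light-phase integral of the fitted
# curve under the species light profile equals a target 12-h amount.
solve_alpha_for_integral <- function(Pmax, Eopt, E_max, target,
                                     interval = c(1e-5, 1)) {
  profile <- diel_light_profile(E_max)
  f <- function(alpha) {
    integrate_diel(pe_curve(alpha, Pmax, Eopt), profile, "light",
                   dt = 0.01) - target
  }
  stats::uniroot(f, interval, tol = 1e-12)$root
}

# Solve the optimum irradiance so the light-phase carbon integral matches a
# target, with alpha and Pmax held at their measured values.
solve_eopt_for_integral <- function(alpha, Pmax, E_max, target,
                                    interval = c(420, 20000)) {
  profile <- diel_light_profile(E_max)
  f <- function(Eopt) {
    integrate_diel(pe_curve(alpha, Pmax, Eopt), profile, "light",
                   dt = 0.01) - target
  }
  stats::uniroot(f, interval, tol = 1e-9)$root
}

# Scale a dimensionless diel shape so that the sparse-sampling trapezoid
# phase total (with nearest-value edge extension) hits `total`.
scale_shape_to_total <- function(t_h, shape, total, bounds) {
  tt <- c(bounds[1L], t_h, bounds[2L])
  vv <- c(shape[1L], shape, shape[length(shape)])
  shape * total / trapz_int(tt, vv)
}

#' Crocosphaera-like synthetic ground truth
#'
#' Preset emulating an open-ocean unicellular diazotroph grown under a
#' 12:12 half-sine cycle peaking at 400 umol photons m^-2 s^-1. The
#' carbon P-E curve uses the measured light-saturation parameter
#' (Ek_C = 331) and hourly assimilation number (0.237); its optimum
#' irradiance is solved so the light-phase carbon integral equals
#' 1.66 umol C per 12 h. The ETR curve uses the measured hourly maximum
#' (1.260) with the initial slope solved so the light-phase ETR integral
#' equals 6.80 umol e- per 12 h. Respiration magnitudes reproduce phase
#' totals of 0.51 (day) and 1.19 (night) umol O2 per 12 h; the gross-O2
#' capacity schedule integrates to 2.04/1.14; the nocturnal N2-fixation
#' schedule peaks at 31.7 nmol (ug Chl)^-1 h^-1 ten hours into the dark
#' and integrates to 77.1 nmol per night. The OD735 proxy peaks at
#' 2.3-fold of the 1L value nine hours into the light and relaxes to
#' 1.4-fold by dawn.
#'
#' @param noise_cv Measurement noise CV (default 0.05).
#' @param seed Master RNG seed.
#' @return A [synthetic_truth()].
#' @export
truth_crocosphaera <- function(noise_cv = 0.05, seed = 1L) {
  E_max <- 400
  alpha_c <- 0.237 / 331
  eopt_c <- solve_eopt_for_integral(alpha_c, 0.237, E_max, target = 1.66)
  alpha_e <- solve_alpha_for_integral(1.260, 1300, E_max, target = 6.80)
  t_day <- seq(1, 11, by = 2)
  t_night <- seq(13, 23, by = 2)
  gross <- data.frame(
    t_h = c(t_day, t_night),
    value = c(scale_shape_to_total(t_day, sin(pi * t_day / 12), 2.04,
                                   c(0, 12)),
              scale_shape_to_total(t_night,
                                   c(0.9, 0.5, 0.2, 0.15, 0.4, 0.8), 1.14,
                                   c(12, 24))))
  n2 <- data.frame(
    t_h = 12:23,
    value = c(0, 0, 0, 0, 0.2, 0.6, 1.6, 5.1, 12, 22, 31.7, 2.6))
  synthetic_truth(
    species = "Crocosphaera",
    pe_etr = pe_curve(alpha_e, 1.260, 1300),
    pe_c = pe_curve(alpha_c, 0.237, eopt_c),
    resp_light = 0.51 / 12, resp_dark = 1.19 / 12,
    gross_o2_schedule = gross, n2fix_schedule = n2,
    fvfm = 0.45, chl = 150,
    od_params = list(t_peak = 9, t_ref = 9, fold_ref = 2.3, fold_end = 1.4),
    noise_cv = noise_cv, seed = seed)
}

#' Cyanothece-like synthetic ground truth
#'
#' Preset emulating a coastal unicellular diazotroph grown under a 12:12
#' half-sine cycle peaking at 130 umol photons m^-2 s^-1. Carbon curve:
#' Ek_C = 88, hourly assimilation number 0.175, optimum irradiance solved
#' for a 1.01 umol C per 12 h light-phase integral. ETR curve: hourly
#' maximum 2.290, initial slope solved for an 8.03 umol e- per 12 h
#' integral. Respiration phase totals 1.10/0.92 umol O2; gross-O2
#' capacity totals 3.09/2.22 with its peak late in the light phase; N2
#' fixation starts at dark onset, peaks at 43.0 nmol (ug Chl)^-1 h^-1 six
#' hours into the dark, integrates to 93.7 nmol per night and ceases
#' about two hours before dawn. OD735 reaches about 1.6-fold at 9 h into
#' the light, peaks near the light-dark transition and ends the night at
#' 1.1-fold.
#'
#' @inheritParams truth_crocosphaera
#' @return A [synthetic_truth()].
#' @export
truth_cyanothece <- function(noise_cv = 0.05, seed = 1L) {
  E_max <- 130
  alpha_c <- 0.175 / 88
  eopt_c <- solve_eopt_for_integral(alpha_c, 0.175, E_max, target = 1.01)
  alpha_e <- solve_alpha_for_integral(2.290, 900, E_max, target = 8.03)
  t_day <- seq(1, 11, by = 2)
  t_night <- seq(13, 23, by = 2)
  gross <- data.frame(
    t_h = c(t_day, t_night),
    value = c(scale_shape_to_total(t_day,
                                   c(0.2, 0.5, 0.8, 1.0, 0.95, 0.4), 3.09,
                                   c(0, 12)),
              scale_shape_to_total(t_night,
                                   c(0.9, 0.7, 0.5, 0.45, 0.55, 0.7), 2.22,
                                   c(12, 24))))
  n2 <- data.frame(
    t_h = 12:23,
    value = c(0, 0.5, 2, 6, 12, 24, 43, 4, 1.7, 0.5, 0, 0))
  synthetic_truth(
    species = "Cyanothece",
    pe_etr = pe_curve(alpha_e, 2.290, 900),
    pe_c = pe_curve(alpha_c, 0.175, eopt_c),
    resp_light = 1.10 / 12, resp_dark = 0.92 / 12,
    gross_o2_schedule = gross, n2fix_schedule = n2,
    fvfm = 0.50, chl = 150,
    od_params = list(t_peak = 11, t_ref = 9, fold_ref = 1.6, fold_end = 1.1),
    noise_cv = noise_cv, seed = seed)
}

#' Fluorescence yields that reproduce a target ETR
#'
#' Inverse of the absorption-method ETR formula: given a target rate, an
#' irradiance and the dark-acclimated yield `fvfm`, returns a yield set
#' whose forward evaluation through [etr_from_yields()] reproduces the
#' target to floating-point accuracy. `F0` is normalized to 1 (only yield
#' ratios enter the formula), `Fm` follows from `fvfm`, and the
#' light-phase yields assume no non-photochemical quenching
#' (`Fm' = Fm`).
#'
#' @param target_etr Desired ETR (umol e- (ug Chl)^-1 h^-1, >= 0).
#' @param E Actinic irradiance (> 0).
#' @param fvfm Dark-acclimated PSII yield in (0, 1).
#' @param chl Chl a (mg m^-3).
#' @param KA Instrument calibration factor (m^-1).
#' @param invert_time_factor Match the convention used by the forward
#'   formula (see [etr_context()]).
#' @return A [frrf_yields()] object.
#' @export
yields_for_etr <- function(target_etr, E, fvfm, chl, KA = 11800,
                           invert_time_factor = FALSE) {
  assert_num(target_etr, "target_etr", lower = 0)
  assert_num(E, "E", lower = 0, strict_lower = TRUE)
  assert_num(fvfm, "fvfm", lower = 0, upper = 1, strict_lower = TRUE)
  tf <- if (isTRUE(invert_time_factor)) 3600 else 1 / 3600
  qP <- target_etr * fvfm / (E * KA / chl * tf)
  if (qP >= 1) {
    dzd_stop("infeasible_target",
             "target ETR implies photochemical yield %.3g >= 1", qP)
  }
  Fm <- 1 / (1 - fvfm)
  frrf_yields(F0 = 1, Fm = Fm, Fp = Fm * (1 - qP), Fmp = Fm, E = E)
}

# Vectorized ladder builder (E = 0 rows get zero photochemistry).
yields_ladder <- function(curve, ladder_E, fvfm, chl, KA,
                          invert_time_factor = FALSE) {
  rows <- lapply(ladder_E, function(E) {
    if (E == 0) {
      Fm <- 1 / (1 - fvfm)
      data.frame(E = 0, F0 = 1, Fm = Fm, Fp = Fm, Fmp = Fm)
    } else {
      y <- yields_for_etr(predict(curve, E = E), E, fvfm, chl, KA,
                          invert_time_factor)
      data.frame(E = E, F0 = y$F0, Fm = y$Fm, Fp = y$Fp, Fmp = y$Fmp)
    }
  })
  do.call(rbind, rows)
}

# OD735 carbon-pool proxy: a state variable integrates true carbon-curve
# photosynthesis along the light schedule minus a consumption term that
# ramps linearly over the light phase (respiration scales with the
# accumulated store) and is constant in the dark. The ramp slope pins the
# OD peak hour, the OD-per-carbon factor pins the peak fold, and the dark
# consumption rate pins the end-of-night fold.
simulate_od <- function(truth, profile, od_dt = 1 / 12) {
  op <- truth$od_params
  t <- seq(0, 24, by = od_dt)
  E <- irradiance_at(pmin(t, 24 * (1 - 1e-12)), profile)
  photo <- predict(truth$pe_c, E = E)
  ramp <- photo[which.min(abs(t - op$t_peak))] / op$t_peak
  light <- t <= profile$photoperiod
  cons <- ifelse(light, ramp * t, 0)
  net <- photo - cons
  C <- c(0, cumsum(diff(t) * (net[-length(net)] + net[-1L]) / 2))
  at <- function(h) C[which.min(abs(t - h))]
  k <- (op$fold_ref - 1) / (at(op$t_ref) - at(1))
  rd <- (at(profile$photoperiod) - at(1) - (op$fold_end - 1) / k) /
    (24 - profile$photoperiod)
  if (rd < 0) {
    dzd_stop("config_error",
             "od_params infeasible: implied dark consumption is negative")
  }
  dark <- t > profile$photoperiod
  C[dark] <- at(profile$photoperiod) - rd * (t[dark] - profile$photoperiod)
  od0 <- 0.35
  data.frame(t_h = t[t < 24], od735 = od0 * (1 + k * (C - at(1)))[t < 24])
}

#' Generate one synthetic diel dataset
#'
#' Produces every table the analysis pipeline consumes - light schedule,
#' OD735 series, one FRRf P-E ladder per sampled light-phase hour, O2
#' electrode series, acetylene-reduction vials and a 14C irradiance
#' series - from a [synthetic_truth()], with multiplicative Gaussian noise
#' (CV = `truth$noise_cv`) applied to every instrument readout through
#' per-instrument RNG streams derived from the master seed. The same seed
#' always yields a bit-identical dataset.
#'
#' @param truth A [synthetic_truth()].
#' @param profile The [diel_light_profile()] of the run.
#' @param constants Optional overrides of the generator constants (ladder
#'   irradiances, sampling hours, 14C and vial constants); see
#'   [default_constants()].
#' @return A `synthetic_diel_dataset`: list of data frames
#'   (`light_series`, `od_series`, `frrf_tables`, `o2_series`,
#'   `ethylene_vials`, `c14_counts`) plus the generating `truth`.
#' @export
generate_diel_dataset <- function(truth, profile, constants = list()) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(profile, "diel_light_profile"))
  cst <- utils::modifyList(default_constants(), constants)
  cv <- truth$noise_cv
  if (cv < 0) dzd_stop("config_error", "noise_cv must be >= 0")
  seed <- truth$seed

  t_light <- seq(0, 24 - cst$light_dt, by = cst$light_dt)
  light <- data.frame(t_h = t_light, E = irradiance_at(t_light, profile))

  od <- simulate_od(truth, profile, od_dt = cst$od_dt)
  od$od735 <- apply_noise(od$od735, cv, seed, "od")

  frrf <- lapply(cst$frrf_times, function(tt) {
    tab <- yields_ladder(truth$pe_etr, cst$frrf_ladder, truth$fvfm,
                         truth$chl, cst$KA, cst$invert_time_factor)
    for (col in c("F0", "Fm", "Fp", "Fmp")) {
      tab[[col]] <- apply_noise(tab[[col]], cv, seed + 7L * tt, "frrf")
    }
    # repair physical ordering that independent noise can break
    tab$Fm <- pmax(tab$Fm, tab$F0 * (1 + 1e-6))
    tab$Fmp <- pmax(tab$Fmp, tab$Fp)
    tab
  })
  names(frrf) <- as.character(cst$frrf_times)

  sched <- truth$gross_o2_schedule
  resp <- ifelse(sched$t_h < truth$photoperiod,
                 truth$resp_light, truth$resp_dark)
  o2 <- data.frame(
    t_h = sched$t_h,
    net_light = apply_noise(sched$value - resp, cv, seed, "o2"),
    resp_dark = apply_noise(resp, cv, seed + 1L, "o2"))

  vial_t <- c(cst$ara_light_times, truth$n2fix_schedule$t_h)
  n2_rate_sched <- c(rep(0, length(cst$ara_light_times)),
                     truth$n2fix_schedule$value)
  chl_ug_ml <- truth$chl / 1000
  eth_nmol <- n2_rate_sched * cst$ara_ratio * chl_ug_ml *
    cst$vial$sample_ml * cst$vial$dt_h
  t_k <- cst$vial$temperature + 273.15
  d_ppm <- eth_nmol * 1e-9 * R_GAS * t_k /
    (cst$vial$pressure * cst$vial$headspace_ml / 1000) * 1e6
  ara <- data.frame(
    vial = sprintf("h%02d", vial_t),
    t_h = vial_t,
    t0_ppm = apply_noise(rep(cst$vial$t0_ppm, length(vial_t)), cv, seed,
                         "ara"),
    t1_ppm = apply_noise(cst$vial$t0_ppm + d_ppm, cv, seed + 1L, "ara"),
    dt_h = cst$vial$dt_h,
    headspace_ml = cst$vial$headspace_ml,
    sample_ml = cst$vial$sample_ml)

  c_rate <- predict(truth$pe_c, E = cst$c14_ladder)
  dpm <- cst$c14$dpm_blank + c_rate * cst$c14$dpm_total * cst$c14$t_inc *
    truth$chl / (cst$c14$dic * cst$c14$discrimination)
  c14 <- data.frame(
    E = cst$c14_ladder,
    dpm = apply_noise(dpm, cv, seed, "c14"),
    dpm_blank = cst$c14$dpm_blank,
    dpm_total = cst$c14$dpm_total)

  structure(list(light_series = light, od_series = od, frrf_tables = frrf,
                 o2_series = o2, ethylene_vials = ara, c14_counts = c14,
                 truth = truth, profile = profile, constants = cst),
            class = "synthetic_diel_dataset")
}

#' Write a synthetic diel dataset as the pipeline's CSV dialects
#'
#' Emits `light.csv`, `od.csv`, one `frrf_<t>.csv` per sampled hour,
#' `o2.csv`, `ara.csv`, `c14.csv` and `truth.json` into `dir`.
#'
#' @param ds A `synthetic_diel_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_diel_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_diel_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dzd_csv(ds$light_series, file.path(dir, "light.csv"))
  write_dzd_csv(ds$od_series, file.path(dir, "od.csv"))
  for (tt in names(ds$frrf_tables)) {
    write_dzd_csv(ds$frrf_tables[[tt]],
                  file.path(dir, sprintf("frrf_%s.csv", tt)))
  }
  write_dzd_csv(ds$o2_series, file.path(dir, "o2.csv"))
  write_dzd_csv(ds$ethylene_vials, file.path(dir, "ara.csv"))
  write_dzd_csv(ds$c14_counts, file.path(dir, "c14.csv"))
  tr <- ds$truth
  curve_list <- function(p) list(alpha = p$alpha, Pmax = p$Pmax,
                                 Eopt = if (is.finite(p$Eopt)) p$Eopt else NA,
                                 Ek = p$Ek)
  jsonlite::write_json(list(
    species = tr$species,
    pe_params_etr = curve_list(tr$pe_etr),
    pe_params_c = curve_list(tr$pe_c),
    resp_light = tr$resp_light, resp_dark = tr$resp_dark,
    n2fix_schedule = tr$n2fix_schedule,
    gross_o2_schedule = tr$gross_o2_schedule,
    fvfm = tr$fvfm, chl = tr$chl, od_params = tr$od_params,
    noise_cv = tr$noise_cv, seed = tr$seed,
    E_max = ds$profile$E_max),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
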