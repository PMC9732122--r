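#' Normalize a diel OD735 series to its value 1 h into the light phase
#'
#' Optical density at 735 nm tracks the cellular carbon pool over the diel
#' cycle; normalizing to the 1L reading (1 h after light onset) removes
#' between-species scattering differences. The anchor value is linearly
#' interpolated when 1L was not sampled exactly.
#'
#' @param t_h Sampling hours since light onset.
#' @param od OD735 readings (> 0 at the anchor).
#' @param anchor_h Anchor hour (default 1).
#' @return Data frame `t_h, od_norm` with `od_norm == 1` at the anchor.
#' @export
normalize_od <- function(t_h, od, anchor_h = 1) {
  assert_num(t_h, "t_h", len = NULL)
  assert_num(od, "od", len = NULL)
  if (length(t_h) != length(od)) {
    dzd_stop("parse_error", "t_h and od differ in length")
  }
  if (anchor_h < min(t_h) || anchor_h > max(t_h)) {
    dzd_stop("normalization_anchor",
             "no samples bracket the %g h normalization anchor", anchor_h)
  }
  ref <- stats::approx(t_h, od, xout = anchor_h, ties = "ordered")$y
  if (!is.finite(ref) || ref <= 0) {
    dzd_stop("normalization_anchor", "anchor OD must be positive")
  }
  data.frame(t_h = t_h, od_norm = od / ref)
}

#' Electron demand per carbon at saturating irradiance
#'
#' `Phi_max = ETRmax / PmB`: the ratio of the maximum electron transport
#' rate to the assimilation number, both Chl-normalized and in the same
#' hourly units.
#'
#' @param etr_max Maximum ETR (umol e- (ug Chl)^-1 h^-1).
#' @param pmB Assimilation number (umol C (ug Chl)^-1 h^-1, > 0).
#' @return Electrons per carbon (dimensionless).
#' @export
phi_max <- function(etr_max, pmB) {
  assert_num(etr_max, "etr_max", lower = 0)
  if (!is.numeric(pmB) || length(pmB) != 1L || !is.finite(pmB) || pmB <= 0) {
    dzd_stop("undefined_ratio", "Phi_max undefined for non-positive PmB")
  }
  etr_max / pmB
}

#' Electron demand per carbon under light limitation
#'
#' `Phi_lim = alpha^ETR / alpha^C`: the ratio of the initial slopes of the
#' ETR and carbon P-E curves.
#'
#' @param alpha_etr Initial slope of the ETR response.
#' @param alpha_c Initial slope of the carbon response (> 0).
#' @return Electrons per carbon (dimensionless).
#' @export
phi_lim <- function(alpha_etr, alpha_c) {
  assert_num(alpha_etr, "alpha_etr", lower = 0)
  if (!is.numeric(alpha_c) || length(alpha_c) != 1L || !is.finite(alpha_c) ||
      alpha_c <= 0) {
    dzd_stop("undefined_ratio", "Phi_lim undefined for non-positive alpha^C")
  }
  alpha_etr / alpha_c
}

#' Respiration as a percentage of gross O2 evolution
#'
#' @param resp_phase Phase-integrated respiration (>= 0).
#' @param gross_phase Phase-integrated gross O2 evolution (> 0).
#' @return List with `raw` (exact percentage) and `pct` (integer-rounded,
#'   the reporting convention).
#' @export
respiration_fraction <- function(resp_phase, gross_phase) {
  assert_num(resp_phase, "resp_phase", lower = 0)
  if (!is.numeric(gross_phase) || length(gross_phase) != 1L ||
      !is.finite(gross_phase) || gross_phase <= 0) {
    dzd_stop("undefined_fraction",
             "respiration fraction undefined for non-positive gross O2")
  }
  raw <- 100 * resp_phase / gross_phase
  list(raw = raw, pct = round(raw))
}

#' Assemble the phase-integrated physiology summary for one species
#'
#' Combines the fitted ETR and carbon P-E curves, the O2 and respiration
#' phase budgets and the N2-fixation budget into a single record shaped
#' like the per-species summary table: light-saturation parameter of
#' carbon uptake (`ek_c`), maximum and diel-integrated ETR, assimilation
#' number and its diel integral, phase O2/respiration/N2 totals, the
#' nitrogenase electron demand and its share of daytime electron
#' transport, and the electron-per-carbon efficiencies `phi_max` /
#' `phi_lim`.
#'
#' `etr_integral_12h` is the light-phase integral of the fitted ETR curve
#' evaluated along the species' own growth light profile ("ETR at the
#' growth irradiance"). `phi_max` is reported both as the ratio of fitted
#' maxima (ratio of means) and, when per-timepoint ETR fits are supplied,
#' as the mean over timepoints of per-timepoint ratios; the two differ
#' whenever ETRmax varies over the day.
#'
#' @param species Species name.
#' @param fit_etr `pe_fit` of the ETR response (hourly units).
#' @param fit_c `pe_fit` of the carbon response (hourly units).
#' @param o2_budget Gross O2 [phase_totals()] budget (umol O2 per 12 h).
#' @param resp_budget Respiration [phase_totals()] budget (magnitudes).
#' @param n2_budget N2 fixation [phase_totals()] budget in umol N2
#'   (ug Chl)^-1 per 12 h.
#' @param profile The species' [diel_light_profile()].
#' @param k [conversion_constants()].
#' @param dt Integration step for diel integrals (h).
#' @param etr_fits_by_time Optional list of per-timepoint ETR `pe_fit`s
#'   for the mean-of-ratios `phi_max` convention.
#' @return A `species_physiology` record (list).
#' @export
species_physiology <- function(species, fit_etr, fit_c, o2_budget,
                               resp_budget, n2_budget, profile,
                               k = conversion_constants(), dt = 0.05,
                               etr_fits_by_time = NULL) {
  stopifnot(inherits(fit_etr, "pe_fit"), inherits(fit_c, "pe_fit"),
            inherits(o2_budget, "phase_budget"),
            inherits(resp_budget, "phase_budget"),
            inherits(n2_budget, "phase_budget"),
            inherits(profile, "diel_light_profile"))
  etr_integral <- integrate_diel(fit_etr, profile, "light", dt = dt)
  pmB_12h <- integrate_diel(fit_c, profile, "light", dt = dt)
  n2_total <- n2_budget$day_total + n2_budget$night_total
  e_dem <- electron_demand(n2_total, k)
  phimax_ratio_of_means <- phi_max(fit_etr$Pmax, fit_c$Pmax)
  phimax_mean_of_ratios <- if (!is.null(etr_fits_by_time)) {
    mean(vapply(etr_fits_by_time,
                function(f) phi_max(f$Pmax, fit_c$Pmax), numeric(1)))
  } else {
    phimax_ratio_of_means
  }
  structure(list(
    species = species,
    ek_c = fit_c$Ek,
    etr_max_h = fit_etr$Pmax,
    etr_max_12h = 12 * fit_etr$Pmax,
    etr_integral_12h = etr_integral,
    pmB_h = fit_c$Pmax,
    pmB_12h = pmB_12h,
    alpha_etr = fit_etr$alpha,
    alpha_c = fit_c$alpha,
    o2_evolution = c(day = o2_budget$day_total,
                     night = o2_budget$night_total),
    respiration = c(day = resp_budget$day_total,
                    night = resp_budget$night_total),
    n2fix = c(day = n2_budget$day_total, night = n2_budget$night_total),
    e_demand = e_dem,
    electron_pct = electron_fraction(e_dem, etr_integral),
    phi_max = phimax_ratio_of_means,
    phi_max_mean_of_ratios = phimax_mean_of_ratios,
    phi_lim = phi_lim(fit_etr$alpha, fit_c$alpha),
    resp_fraction_day = respiration_fraction(resp_budget$day_total,
                                             o2_budget$day_total),
    E_max = profile$E_max),
    class = "species_physiology")
}

#' @export
print.species_physiology <- function(x, ...) {
  cat(sprintf("%s physiology (Chl-normalized, per 12-h phase):\n", x$species))
  cat(sprintf("  Ek_C %.4g; ETRmax %.4g h-1; PmB %.4g h-1\n",
              x$ek_c, x$etr_max_h, x$pmB_h))
  cat(sprintf("  ETR integral %.4g; C integral %.4g (light phase)\n",
              x$etr_integral_12h, x$pmB_12h))
  cat(sprintf("  O2 evolution day/night %.4g/%.4g; respiration %.4g/%.4g\n",
              x$o2_evolution[["day"]], x$o2_evolution[["night"]],
              x$respiration[["day"]], x$respiration[["night"]]))
  cat(sprintf("  N2 fixation day/night %.4g/%.4g umol; e- demand %.4g (%.3g%% of daytime ETR)\n",
              x$n2fix[["day"]], x$n2fix[["night"]], x$e_demand,
              x$electron_pct))
  cat(sprintf("  Phi_max %.4g (mean-of-ratios %.4g); Phi_lim %.4g e- C-1; day respiration %d%% of gross O2\n",
              x$phi_max, x$phi_max_mean_of_ratios, x$phi_lim,
              x$resp_fraction_day$pct))
  invisible(x)
}

#' Cross-species comparison ratios
#'
#' Fold differences and percentages comparing species `b` to species `a`
#' in the direction the physiology contrast is usually quoted: light-phase
#' respiration fold (`b/a`), total (day + night) respiration fold, and the
#' daily N2 fixation of `a` as a percentage of `b`'s. Raw values are kept
#' alongside the reporting-precision roundings (folds to 1 decimal,
#' percentages to integers).
#'
#' @param a,b `species_physiology` records (`a` = reference numerator for
#'   the N2 percentage, `b` = numerator for the respiration folds).
#' @return A `species_comparison` list.
#' @export
cross_species_ratios <- function(a, b) {
  stopifnot(inherits(a, "species_physiology"),
            inherits(b, "species_physiology"))
  div <- function(num, den, what) {
    if (den == 0) dzd_stop("undefined_ratio", "%s undefined (zero divisor)",
                           what)
    num / den
  }
  resp_light_fold <- div(b$respiration[["day"]], a$respiration[["day"]],
                         "light-phase respiration fold")
  resp_total_fold <- div(sum(b$respiration), sum(a$respiration),
                         "total respiration fold")
  n2_pct <- 100 * div(sum(a$n2fix), sum(b$n2fix), "daily N2 percentage")
  structure(list(
    species = c(a = a$species, b = b$species),
    resp_light_fold = list(raw = resp_light_fold,
                           rounded = round(resp_light_fold, 1)),
    resp_total_fold = list(raw = resp_total_fold,
                           rounded = round(resp_total_fold, 1)),
    n2_fixation_pct = list(raw = n2_pct, rounded = round(n2_pct))),
    class = "species_comparison")
}

#' Write the per-species physiology summary table
#'
#' One row per (species, parameter) with Day/Night columns, mirroring the
#' phase-resolved summary-table layout. Values are written unrounded.
#'
#' @param phys_list List of `species_physiology` records.
#' @param path Output CSV path.
#' @return The table (invisibly).
#' @export
write_summary_table <- function(phys_list, path) {
  row <- function(p) {
    data.frame(
      species = p$species,
      parameter = c("Ek_C", "ETR_max_h", "ETR_integral", "O2_evolution",
                    "Respiration", "PmB_h", "PmB_integral", "N2_fixation",
                    "e_demand_N2", "electron_pct", "Phi_max", "Phi_lim"),
      units = c("umol quanta m-2 s-1", "umol e (ug Chl)-1 h-1",
                "umol e (ug Chl)-1 12 h-1", "umol O2 (ug Chl)-1 12 h-1",
                "umol O2 (ug Chl)-1 12 h-1", "umol C (ug Chl)-1 h-1",
                "umol C (ug Chl)-1 12 h-1", "umol N2 (ug Chl)-1 12 h-1",
                "umol e (ug Chl)-1 12 h-1", "%", "e C-1", "e C-1"),
      day = c(p$ek_c, p$etr_max_h, p$etr_integral_12h,
              p$o2_evolution[["day"]], p$respiration[["day"]], p$pmB_h,
              p$pmB_12h, p$n2fix[["day"]], p$e_demand, p$electron_pct,
              p$phi_max, p$phi_lim),
      night = c(NA, NA, NA, p$o2_evolution[["night"]],
                p$respiration[["night"]], NA, NA, p$n2fix[["night"]],
                NA, NA, NA, NA))
  }
  df <- do.call(rbind, lapply(phys_list, row))
  write_dzd_csv(df, path)
  invisible(df)
}

#' Write a species comparison as JSON
#' @param cmp A `species_comparison`.
#' @param path Output path.
#' @export
write_comparison <- function(cmp, path) {
  jsonlite::write_json(unclass(cmp), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
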