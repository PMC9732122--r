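#' Conversion constants for the acetylene reduction assay
#'
#' @param ara_ratio Theoretical molar ratio of acetylene reduced (ethylene
#'   produced) per N2 fixed; default 4.
#' @param electrons_per_n2 Electrons required by nitrogenase to fix one N2;
#'   default 8.
#' @return A `conversion_constants` object.
#' @export
conversion_constants <- function(ara_ratio = 4, electrons_per_n2 = 8) {
  assert_num(ara_ratio, "ara_ratio", lower = 0, strict_lower = TRUE)
  assert_num(electrons_per_n2, "electrons_per_n2", lower = 0,
             strict_lower = TRUE)
  structure(list(ara_ratio = ara_ratio, electrons_per_n2 = electrons_per_n2),
            class = "conversion_constants")
}

# Ideal gas constant, L atm mol^-1 K^-1.
R_GAS <- 0.08206

#' Ethylene production rate from a headspace vial
#'
#' Converts the change in headspace ethylene mixing ratio over the
#' incubation into moles via the ideal-gas law at the vial temperature and
#' pressure, then normalizes by incubation time and total Chl a in the
#' liquid sample. Ethylene dissolved in the liquid phase is neglected
#' (headspace-only accounting); a Bunsen-coefficient correction can be
#' supplied for waters where dissolution matters.
#'
#' @param c2h4_t0,c2h4_t1 Headspace ethylene mixing ratios at the start and
#'   end of the incubation (ppm v/v, >= 0). Vectorized.
#' @param headspace_ml Headspace volume (mL, > 0).
#' @param sample_ml Liquid sample volume (mL, > 0).
#' @param t_inc Incubation duration (h, > 0).
#' @param chl Chl a concentration of the sample (ug mL^-1, > 0).
#' @param temperature Vial temperature (deg C, default 28).
#' @param pressure Vial pressure (atm, default 1).
#' @param bunsen Optional Bunsen solubility coefficient; when non-zero the
#'   dissolved ethylene `bunsen * sample_ml` is added to the effective gas
#'   volume. Default 0 (off).
#' @return Rate(s), nmol C2H4 (ug Chl a)^-1 h^-1. Negative ethylene changes
#'   clamp to zero with a warning.
#' @export
ethylene_production_rate <- function(c2h4_t0, c2h4_t1, headspace_ml,
                                     sample_ml, t_inc, chl,
                                     temperature = 28, pressure = 1,
                                     bunsen = 0) {
  assert_num(c2h4_t0, "c2h4_t0", lower = 0, len = NULL)
  assert_num(c2h4_t1, "c2h4_t1", lower = 0, len = NULL)
  assert_num(headspace_ml, "headspace_ml", lower = 0, strict_lower = TRUE,
             len = NULL)
  assert_num(sample_ml, "sample_ml", lower = 0, strict_lower = TRUE,
             len = NULL)
  assert_num(t_inc, "t_inc", lower = 0, strict_lower = TRUE, len = NULL)
  assert_num(chl, "chl", lower = 0, strict_lower = TRUE, len = NULL)
  assert_num(bunsen, "bunsen", lower = 0)
  d_ppm <- c2h4_t1 - c2h4_t0
  if (any(d_ppm < 0)) {
    dzd_warn("negative_uptake",
             "ethylene decreased in %d vial(s); clamping rate to 0",
             sum(d_ppm < 0))
    d_ppm <- pmax(d_ppm, 0)
  }
  vol_l <- (headspace_ml + bunsen * sample_ml) / 1000
  t_k <- temperature + 273.15
  mol <- d_ppm * 1e-6 * pressure * vol_l / (R_GAS * t_k)
  mol * 1e9 / t_inc / (chl * sample_ml)
}

#' N2 fixation rate from an ethylene production rate
#'
#' Applies the theoretical molar ratio of acetylene reduction to N2
#' reduction (default 4:1).
#'
#' @param ethylene_rate Ethylene production rate(s) (>= 0), nmol C2H4
#'   (ug Chl a)^-1 h^-1.
#' @param k A [conversion_constants()].
#' @return Rate(s), nmol N2 (ug Chl a)^-1 h^-1.
#' @export
n2_rate <- function(ethylene_rate, k = conversion_constants()) {
  assert_num(ethylene_rate, "ethylene_rate", lower = 0, len = NULL)
  ethylene_rate / k$ara_ratio
}

#' Nitrogenase electron demand of a phase-integrated N2 fixation amount
#'
#' @param daily_n2 Phase-integrated N2 fixation (umol N2 (ug Chl a)^-1 per
#'   phase, >= 0).
#' @param k A [conversion_constants()]; 8 electrons per N2 by default.
#' @return Electron amount, umol e- (ug Chl a)^-1 per phase.
#' @export
electron_demand <- function(daily_n2, k = conversion_constants()) {
  assert_num(daily_n2, "daily_n2", lower = 0, len = NULL)
  k$electrons_per_n2 * daily_n2
}

#' Percentage of transported electrons devoted to N2 fixation
#'
#' @param demand Electron demand for N2 fixation (umol e- per phase).
#' @param etr_integral Phase-integrated electron transport (umol e- per
#'   phase, > 0).
#' @return Percentage (0-100 scale, not rounded).
#' @export
electron_fraction <- function(demand, etr_integral) {
  assert_num(demand, "demand", lower = 0)
  if (!is.numeric(etr_integral) || length(etr_integral) != 1L ||
      !is.finite(etr_integral) || etr_integral <= 0) {
    dzd_stop("undefined_fraction",
             "electron fraction undefined for non-positive ETR integral")
  }
  100 * demand / etr_integral
}

#' Read an acetylene-reduction vial CSV
#'
#' Expected columns: `vial,t_h,t0_ppm,t1_ppm,dt_h,headspace_ml,sample_ml`
#' (`t_h` is the hour the incubation started, used to place the rate on the
#' diel axis).
#' @param path File path.
#' @return Data frame.
#' @export
read_ara <- function(path) {
  read_dzd_csv(path, c("vial", "t_h", "t0_ppm", "t1_ppm", "dt_h",
                       "headspace_ml", "sample_ml"))
}
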