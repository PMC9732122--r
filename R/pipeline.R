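#' Generator and analysis constants with their defaults
#'
#' Physical constants, instrument layouts and numerical settings shared by
#' the synthetic generator and the analysis stages. Any element can be
#' overridden through the run config.
#'
#' Defaults: FRRf calibration factor `KA = 11800` m^-1 with the published
#' time factor as printed; 11-step P-E ladders spanning 0 to ~1500 umol
#' photons m^-2 s^-1; FRRf sampling at 1, 3, 5, 7, 9, 11 h into the light
#' phase; O2 electrode sampling every 2 h; acetylene vials of 10 mL
#' headspace over 5 mL sample incubated 1 h at 28 deg C; 14C incubations
#' of 0.5 h with 1.11e6 dpm added (0.5 uCi in 1 mL), seawater DIC of
#' 2050 umol L^-1 and isotope discrimination 1.05; diel integration step
#' 0.05 h.
#'
#' @return Nested list of constants.
#' @export
default_constants <- function() {
  list(
    KA = 11800,
    invert_time_factor = FALSE,
    dt = 0.05,
    ara_ratio = 4,
    electrons_per_n2 = 8,
    budget_method = "trapezoid",
    c14 = list(t_inc = 0.5, dic = 2050, discrimination = 1.05,
               dpm_total = 1.11e6, dpm_blank = 200),
    vial = list(headspace_ml = 10, sample_ml = 5, dt_h = 1,
                temperature = 28, pressure = 1, t0_ppm = 0.1, bunsen = 0),
    frrf_ladder = c(0, 30, 60, 120, 220, 350, 520, 740, 980, 1230, 1495),
    c14_ladder = c(0, 30, 60, 120, 220, 350, 520, 750, 1000, 1250, 1528),
    frrf_times = c(1, 3, 5, 7, 9, 11),
    ara_light_times = seq(1, 11, by = 2),
    od_dt = 1 / 12,
    light_dt = 0.1)
}

#' Default run configuration
#'
#' Synthetic mode with the two species presets under their respective
#' growth irradiances (400 and 130 umol photons m^-2 s^-1).
#'
#' @param output_dir,input_dir Directories for results and datasets.
#' @param seed Master seed.
#' @param noise_cv Measurement noise CV for synthetic mode.
#' @return A `run_config` list.
#' @export
default_config <- function(output_dir = tempfile("diazodiel_out"),
                           input_dir = tempfile("diazodiel_in"),
                           seed = 1L, noise_cv = 0) {
  structure(list(
    mode = "synthetic",
    input_dir = input_dir,
    output_dir = output_dir,
    seed = as.integer(seed),
    noise_cv = noise_cv,
    constants = default_constants(),
    species = list(
      crocosphaera = list(preset = "crocosphaera", E_max = 400, chl = 150),
      cyanothece = list(preset = "cyanothece", E_max = 130, chl = 150)),
    cfm = list(k_scale = 1, n_grid = 101)),
    class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file; unspecified fields fall back to
#'   [default_config()] values (constants are merged recursively).
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) dzd_stop("parse_error", "config not found: %s", path)
  raw <- yaml::read_yaml(path)
  cfg <- unclass(default_config())
  cfg$species <- NULL
  cfg <- utils::modifyList(cfg, raw)
  if (is.null(cfg$species)) cfg$species <- default_config()$species
  structure(cfg, class = "run_config")
}

finding <- function(field, severity, message) {
  data.frame(field = field, severity = severity, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a run configuration
#'
#' Pure check: returns a data frame of findings (`field, severity,
#' message`), empty when the config is valid; never mutates or throws.
#'
#' @param cfg A `run_config`.
#' @return Data frame of findings (zero rows when valid).
#' @export
validate_config <- function(cfg) {
  f <- finding(character(), character(), character())
  add <- function(...) f <<- rbind(f, finding(...))
  if (is.null(cfg$mode) || !cfg$mode %in% c("synthetic", "csv")) {
    add("mode", "error", "mode must be 'synthetic' or 'csv'")
  }
  if (identical(cfg$mode, "synthetic") &&
      (is.null(cfg$seed) || is.na(suppressWarnings(as.integer(cfg$seed))))) {
    add("seed", "error", "an integer seed is required in synthetic mode")
  }
  if (!is.null(cfg$noise_cv) && cfg$noise_cv < 0) {
    add("noise_cv", "error", "noise_cv must be >= 0")
  }
  cst <- cfg$constants %||% list()
  num_pos <- function(name, val) {
    if (!is.null(val) && (!is.numeric(val) || val <= 0)) {
      add(name, "error", sprintf("%s must be > 0", name))
    }
  }
  num_pos("constants.KA", cst$KA)
  num_pos("constants.ara_ratio", cst$ara_ratio)
  num_pos("constants.electrons_per_n2", cst$electrons_per_n2)
  num_pos("constants.c14.dic", cst$c14$dic)
  num_pos("constants.c14.t_inc", cst$c14$t_inc)
  if (!is.null(cst$dt) && cst$dt > 0.25) {
    add("constants.dt", "warning",
        "integration step exceeds the 0.25 h cap; integrals may be coarse")
  }
  if (is.null(cfg$species) || length(cfg$species) < 1L) {
    add("species", "error", "at least one species block is required")
  } else {
    for (nm in names(cfg$species)) {
      sp <- cfg$species[[nm]]
      if (is.null(sp$E_max) || sp$E_max <= 0) {
        add(sprintf("species.%s.E_max", nm), "error",
            "a positive growth E_max is required")
      }
      if (is.null(sp$chl) || sp$chl <= 0) {
        add(sprintf("species.%s.chl", nm), "error",
            "a positive Chl a concentration is required")
      }
      if (identical(cfg$mode, "synthetic") &&
          !(sp$preset %||% "") %in% c("crocosphaera", "cyanothece")) {
        add(sprintf("species.%s.preset", nm), "error",
            "synthetic mode needs preset 'crocosphaera' or 'cyanothece'")
      }
    }
  }
  f
}

truth_preset <- function(name, noise_cv, seed) {
  switch(name,
         crocosphaera = truth_crocosphaera(noise_cv = noise_cv, seed = seed),
         cyanothece = truth_cyanothece(noise_cv = noise_cv, seed = seed),
         dzd_stop("config_error", "unknown preset '%s'", name))
}

#' Analyze one species' diel dataset directory
#'
#' Reads the CSV tables of one photobioreactor run through the package
#' readers, runs every analysis stage (per-hour ETR P-E fits, carbon P-E
#' fit, gross-O2 and respiration phase budgets, acetylene-to-N2 rates and
#' their budget, OD735 normalization) and assembles the
#' [species_physiology()] record. Per-stage artifacts (`pe_fit.csv`,
#' `phase_budgets.csv`, `n2fix_rates.csv`, `od_normalized.csv`) are
#' written to `out_dir` when given.
#'
#' @param dir Directory holding `frrf_<t>.csv`, `o2.csv`, `ara.csv`,
#'   `c14.csv`, `od.csv`.
#' @param species Species label.
#' @param E_max Growth-light maximum irradiance for the diel integrals.
#' @param chl Chl a concentration of the culture (mg m^-3).
#' @param constants Constants list (see [default_constants()]).
#' @param out_dir Optional artifact directory.
#' @return A list: `physiology` ([species_physiology()]), `fit_etr`,
#'   `fit_c`, `etr_fits`, `budgets`, `n2_series`, `od_norm`, `od_peak`.
#' @export
analyze_species_dir <- function(dir, species, E_max, chl,
                                constants = default_constants(),
                                out_dir = NULL) {
  cst <- utils::modifyList(default_constants(), constants)
  profile <- diel_light_profile(E_max)
  ctx <- etr_context(KA = cst$KA, chl = chl,
                     invert_time_factor = cst$invert_time_factor)
  k <- conversion_constants(cst$ara_ratio, cst$electrons_per_n2)

  frrf_files <- sort(list.files(dir, pattern = "^frrf_.*\\.csv$",
                                full.names = TRUE))
  if (!length(frrf_files)) {
    dzd_stop("parse_error", "no frrf_<t>.csv ladders found in %s", dir)
  }
  t_frrf <- as.numeric(sub("^frrf_(.*)\\.csv$", "\\1", basename(frrf_files)))
  ord <- order(t_frrf)
  frrf_files <- frrf_files[ord]; t_frrf <- t_frrf[ord]
  etr_fits <- lapply(frrf_files, function(f) fit_etr_ladder(read_frrf(f), ctx))
  names(etr_fits) <- sprintf("ETR_%g", t_frrf)
  mean_eopt <- if (all(vapply(etr_fits, function(f) is.finite(f$Eopt),
                              logical(1)))) {
    mean(vapply(etr_fits, `[[`, numeric(1), "Eopt"))
  } else {
    Inf
  }
  fit_etr <- pe_curve(mean(vapply(etr_fits, `[[`, numeric(1), "alpha")),
                      mean(vapply(etr_fits, `[[`, numeric(1), "Pmax")),
                      mean_eopt)

  fit_c <- fit_carbon_pe(read_c14(file.path(dir, "c14.csv")),
                         t_inc = cst$c14$t_inc, dic = cst$c14$dic,
                         chl = chl,
                         discrimination = cst$c14$discrimination)

  o2 <- read_o2(file.path(dir, "o2.csv"))
  gross <- rate_timeseries(o2$t_h, gross_o2(o2$net_light, o2$resp_dark),
                           label = "gross_o2")
  resp <- rate_timeseries(o2$t_h, o2$resp_dark, label = "respiration")
  o2_budget <- phase_totals(gross, method = cst$budget_method)
  resp_budget <- phase_totals(resp, method = cst$budget_method)

  ara <- read_ara(file.path(dir, "ara.csv"))
  eth <- ethylene_production_rate(
    ara$t0_ppm, ara$t1_ppm, ara$headspace_ml, ara$sample_ml,
    t_inc = ara$dt_h, chl = chl / 1000,
    temperature = cst$vial$temperature, pressure = cst$vial$pressure,
    bunsen = cst$vial$bunsen)
  n2_nmol <- n2_rate(eth, k)
  ord2 <- order(ara$t_h)
  n2_series <- rate_timeseries(ara$t_h[ord2], n2_nmol[ord2] / 1000,
                               label = "n2fix")
  n2_budget <- phase_totals(n2_series, method = cst$budget_method)

  od <- read_dzd_csv(file.path(dir, "od.csv"), c("t_h", "od735"))
  od_norm <- normalize_od(od$t_h, od$od735)
  peak_i <- which.max(od_norm$od_norm)

  phys <- species_physiology(
    species, fit_etr, fit_c, o2_budget, resp_budget, n2_budget, profile,
    k = k, dt = cst$dt, etr_fits_by_time = etr_fits)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pe_fit(c(etr_fits, list(C14 = fit_c)),
                 file.path(out_dir, "pe_fit.csv"),
                 t_h = c(t_frrf, NA))
    write_phase_budgets(list(gross_o2 = o2_budget, respiration = resp_budget,
                             n2fix = n2_budget),
                        file.path(out_dir, "phase_budgets.csv"), species)
    write_dzd_csv(data.frame(t_h = n2_series$t_h,
                             rate_nmol_per_ugchl_h = n2_series$value * 1000),
                  file.path(out_dir, "n2fix_rates.csv"))
    write_dzd_csv(od_norm, file.path(out_dir, "od_normalized.csv"))
  }

  list(physiology = phys, fit_etr = fit_etr, fit_c = fit_c,
       etr_fits = etr_fits,
       budgets = list(gross_o2 = o2_budget, respiration = resp_budget,
                      n2fix = n2_budget),
       n2_series = n2_series, od_norm = od_norm,
       od_peak = list(fold = od_norm$od_norm[peak_i],
                      t_h = od_norm$t_h[peak_i]))
}

#' Run the full diel physiology pipeline
#'
#' In `synthetic` mode, generates one seeded dataset per configured
#' species preset into `input_dir` and analyzes it; in `csv` mode,
#' analyzes existing per-species directories under `input_dir`. Assembles
#' the per-species physiology summary, the cross-species comparison, maps
#' the measured budgets onto CFM-CC parameters and runs the two-species
#' competition. Writes `summary_table1.csv`, `comparison.json`,
#' `competition.csv`, `crossover.json`, per-species stage artifacts and a
#' provenance log; identical config and seed give byte-identical outputs.
#'
#' @param cfg A `run_config` ([default_config()] or [load_run_config()]).
#' @return A `summary_report` list: `physiology` (per species),
#'   `comparison`, `competition`, `crossover`, `summary_table`,
#'   `od_peaks`, `paths`.
#' @export
run_pipeline <- function(cfg) {
  findings <- validate_config(cfg)
  errs <- findings[findings$severity == "error", , drop = FALSE]
  if (nrow(errs)) {
    dzd_stop("config_error", "invalid config: %s",
             paste(sprintf("%s (%s)", errs$message, errs$field),
                   collapse = "; "),
             data = findings)
  }
  cst <- utils::modifyList(default_constants(), cfg$constants %||% list())
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  log_lines <- c(
    sprintf("diazodiel %s", as.character(utils::packageVersion("diazodiel"))),
    sprintf("mode=%s seed=%d noise_cv=%g", cfg$mode, cfg$seed,
            cfg$noise_cv %||% 0),
    sprintf("config_sha=%s", config_hash(cfg)))

  species_names <- names(cfg$species)
  results <- list()
  for (i in seq_along(species_names)) {
    nm <- species_names[i]
    sp <- cfg$species[[nm]]
    sp_dir <- file.path(cfg$input_dir, nm)
    if (identical(cfg$mode, "synthetic")) {
      truth <- truth_preset(sp$preset, noise_cv = cfg$noise_cv %||% 0,
                            seed = cfg$seed + 1000L * (i - 1L))
      ds <- generate_diel_dataset(truth, diel_light_profile(sp$E_max),
                                  constants = cst)
      write_diel_dataset(ds, sp_dir)
      log_lines <- c(log_lines,
                     sprintf("simulate species=%s preset=%s seed=%d", nm,
                             sp$preset, truth$seed))
    }
    res <- analyze_species_dir(sp_dir, species = nm, E_max = sp$E_max,
                               chl = sp$chl, constants = cst,
                               out_dir = file.path(cfg$output_dir, nm))
    log_lines <- c(log_lines, sprintf(
      "analyze species=%s Ek_C=%.6g ETRint=%.6g n2_night=%.6g",
      nm, res$physiology$ek_c, res$physiology$etr_integral_12h,
      res$physiology$n2fix[["night"]]))
    results[[nm]] <- res
  }

  phys <- lapply(results, `[[`, "physiology")
  summary_df <- write_summary_table(
    phys, file.path(cfg$output_dir, "summary_table1.csv"))

  comparison <- NULL
  competition <- NULL
  crossover <- NULL
  if (length(phys) >= 2L) {
    comparison <- cross_species_ratios(phys[[1L]], phys[[2L]])
    write_comparison(comparison, file.path(cfg$output_dir, "comparison.json"))
    params <- cfm_params_from_config(cfg, phys)
    competition <- run_competition(params[[1L]], params[[2L]],
                                   n_grid = cfg$cfm$n_grid %||% 101L)
    crossover <- attr(competition, "crossover")
    write_competition(competition, file.path(cfg$output_dir,
                                             "competition.csv"))
    write_crossover(competition, file.path(cfg$output_dir, "crossover.json"))
    log_lines <- c(log_lines, sprintf(
      "compete a=%s b=%s crossover=%s", params[[1L]]$species,
      params[[2L]]$species,
      if (crossover$status == "crossover") sprintf("%.6g", crossover$fN)
      else crossover$status))
  }

  writeLines(log_lines, file.path(cfg$output_dir, "log.txt"))
  structure(list(physiology = phys, comparison = comparison,
                 competition = competition, crossover = crossover,
                 summary_table = summary_df,
                 od_peaks = lapply(results, `[[`, "od_peak"),
                 results = results,
                 paths = list(output = cfg$output_dir,
                              input = cfg$input_dir)),
            class = "summary_report")
}

# CFM parameters either stated in the config or derived from measurements.
cfm_params_from_config <- function(cfg, phys) {
  stated <- cfg$cfm$species
  lapply(seq_along(phys), function(i) {
    nm <- names(phys)[i]
    if (!is.null(stated[[nm]])) {
      cfm_params(nm, stated[[nm]]$pmax, stated[[nm]]$m)
    } else {
      cfm_from_physiology(phys[[i]], k_scale = cfg$cfm$k_scale %||% 1)
    }
  })
}

# Hash of the scientific configuration only: run locations (input/output
# directories) are excluded so identical analyses hash identically.
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$input_dir <- NULL
  cfg$output_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}
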