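# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Noise-free synthetic run of both species presets through the full
# pipeline (memoized: several test files inspect the same run).
noise_free_report <- function() {
  if (is.null(.fixtures$report)) {
    cfg <- default_config(seed = 42L, noise_cv = 0)
    .fixtures$cfg <- cfg
    .fixtures$report <- run_pipeline(cfg)
  }
  .fixtures$report
}

noise_free_cfg <- function() {
  noise_free_report()
  .fixtures$cfg
}

# Reference trapezoid, independent of the package internals.
trapz_ref <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Species physiology records assembled from the published phase totals
# (desk-scale inputs, no simulation): preset P-E curves plus budgets set
# to the printed per-12-h values.
phys_from_printed <- function(which = c("crocosphaera", "cyanothece")) {
  which <- match.arg(which)
  budget <- function(day, night, label) {
    structure(list(day_total = day, night_total = night, label = label,
                   method = "trapezoid"), class = "phase_budget")
  }
  if (which == "crocosphaera") {
    tr <- truth_crocosphaera(noise_cv = 0, seed = 1L)
    species_physiology(
      "Crocosphaera", tr$pe_etr, tr$pe_c,
      o2_budget = budget(2.04, 1.14, "gross_o2"),
      resp_budget = budget(0.51, 1.19, "respiration"),
      n2_budget = budget(0, 0.0771, "n2fix"),
      profile = diel_light_profile(400))
  } else {
    tr <- truth_cyanothece(noise_cv = 0, seed = 1L)
    species_physiology(
      "Cyanothece", tr$pe_etr, tr$pe_c,
      o2_budget = budget(3.09, 2.22, "gross_o2"),
      resp_budget = budget(1.10, 0.92, "respiration"),
      n2_budget = budget(0, 0.0937, "n2fix"),
      profile = diel_light_profile(130))
  }
}
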