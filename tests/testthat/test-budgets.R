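test_that("OD normalization anchors at the 1L value", {
  t <- seq(0, 23.9, by = 0.5)
  od <- 0.4 + 0.01 * t
  n <- normalize_od(t, od)
  expect_equal(n$od_norm[t == 1], 1)
  flat <- normalize_od(t, rep(0.37, length(t)))
  expect_true(all(flat$od_norm == 1))
  # anchor interpolated when 1L was not sampled exactly
  n2 <- normalize_od(c(0.5, 1.5, 3), c(2, 4, 6))
  expect_equal(n2$od_norm[2], 4 / 3)
  expect_error(normalize_od(c(2, 3), c(1, 2)),
               class = "dzd_normalization_anchor")
})

test_that("electron-per-carbon efficiencies reproduce published values", {
  expect_equal(round(phi_max(1.260, 0.237), 1), 5.3)
  expect_equal(phi_max(2.290, 0.175), 13.0857, tolerance = 1e-4)
  expect_equal(phi_max(0.8, 0.8), 1)
  expect_error(phi_max(1, 0), class = "dzd_undefined_ratio")

  expect_equal(phi_lim(0.002, 0.002), 1)
  expect_equal(round(phi_lim(0.0074, 0.002), 1), 3.7)
  expect_equal(phi_lim(0.0074 * 3, 0.002 * 3), phi_lim(0.0074, 0.002),
               tolerance = 1e-12)
  expect_error(phi_lim(1, 0), class = "dzd_undefined_ratio")
})

test_that("respiration fractions match the published percentages", {
  expect_equal(respiration_fraction(1.10, 3.09)$pct, 36)
  expect_equal(respiration_fraction(0.51, 2.04)$pct, 25)
  expect_equal(respiration_fraction(0, 2)$pct, 0)
  expect_error(respiration_fraction(1, 0), class = "dzd_undefined_fraction")
})

test_that("cross-species ratios recover the published contrasts", {
  cro <- phys_from_printed("crocosphaera")
  cya <- phys_from_printed("cyanothece")
  cmp <- cross_species_ratios(cro, cya)
  expect_equal(cmp$resp_light_fold$raw, 1.10 / 0.51, tolerance = 1e-12)
  expect_equal(cmp$resp_total_fold$rounded, 1.2)
  expect_equal(cmp$n2_fixation_pct$rounded, 82)
  same <- cross_species_ratios(cro, cro)
  expect_equal(same$resp_light_fold$raw, 1)
  expect_equal(same$resp_total_fold$raw, 1)
  expect_equal(same$n2_fixation_pct$raw, 100)
})

test_that("ratio operations are invariant under common unit changes", {
  for (s in c(0.001, 1, 1000)) {
    expect_equal(phi_max(1.26 * s, 0.237 * s), phi_max(1.26, 0.237),
                 tolerance = 1e-12)
    expect_equal(respiration_fraction(0.51 * s, 2.04 * s)$raw,
                 respiration_fraction(0.51, 2.04)$raw, tolerance = 1e-12)
  }
})

test_that("the summary table round-trips through CSV unchanged", {
  cro <- phys_from_printed("crocosphaera")
  cya <- phys_from_printed("cyanothece")
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_summary_table(list(cro, cya), path)
  back <- read.csv(path)
  expect_equal(back$day, df$day, tolerance = 1e-12)
  expect_equal(back$night, df$night, tolerance = 1e-12)
  expect_identical(back$parameter, df$parameter)
})

test_that("assembled physiology reflects its inputs coherently", {
  cro <- phys_from_printed("crocosphaera")
  expect_equal(cro$ek_c, 331, tolerance = 1e-9)
  expect_equal(cro$etr_integral_12h, 6.80, tolerance = 1e-3)
  expect_equal(cro$pmB_12h, 1.66, tolerance = 1e-3)
  expect_equal(cro$e_demand, 8 * 0.0771, tolerance = 1e-12)
  expect_equal(round(cro$electron_pct, 1), 9.1)
  expect_equal(cro$resp_fraction_day$pct, 25)
  cya <- phys_from_printed("cyanothece")
  expect_equal(cya$ek_c, 88, tolerance = 1e-9)
  expect_equal(round(cya$electron_pct, 1), 9.3)
  expect_equal(cya$resp_fraction_day$pct, 36)
})
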