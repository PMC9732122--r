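test_that("yield inversion round-trips through the forward formula", {
  ctx <- etr_context(chl = 150)
  set.seed(99)
  for (i in 1:100) {
    E <- runif(1, 10, 1500)
    # any target below the feasibility ceiling (photochemical yield < 1)
    x_max <- E * 11800 / (0.45 * 150 * 3600)
    x <- runif(1, 0, 0.95 * x_max)
    y <- yields_for_etr(x, E, fvfm = 0.45, chl = 150)
    expect_equal(etr_from_yields(y, ctx), x, tolerance = 1e-10)
  }
})

test_that("yield inversion encodes fvfm and handles edge targets", {
  y <- yields_for_etr(0.5, 200, fvfm = 0.5, chl = 150)
  expect_equal(y$Fm, 2 * y$F0)                    # Fv/Fm = 0.5
  y0 <- yields_for_etr(0, 200, fvfm = 0.45, chl = 150)
  expect_equal(y0$Fp, y0$Fmp)                     # zero photochemistry
  # implied photochemical yield >= 1 is infeasible
  expect_error(yields_for_etr(1000, 1, fvfm = 0.45, chl = 150),
               class = "dzd_infeasible_target")
})

test_that("same seed gives byte-identical written datasets", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  prof <- diel_light_profile(400)
  write_diel_dataset(generate_diel_dataset(
    truth_crocosphaera(noise_cv = 0.08, seed = 7L), prof), d1)
  write_diel_dataset(generate_diel_dataset(
    truth_crocosphaera(noise_cv = 0.08, seed = 7L), prof), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6), label = f)
  }
  # and a different seed changes the noisy readouts
  d3 <- withr::local_tempdir()
  write_diel_dataset(generate_diel_dataset(
    truth_crocosphaera(noise_cv = 0.08, seed = 8L), prof), d3)
  expect_false(identical(readBin(file.path(d1, "od.csv"), "raw", 2e6),
                         readBin(file.path(d3, "od.csv"), "raw", 2e6)))
})

test_that("negative noise CV is rejected", {
  expect_error(truth_crocosphaera(noise_cv = -0.1, seed = 1L),
               class = "dzd_config_error")
})

test_that("schedules must keep N2 fixation out of the light phase", {
  tr <- truth_crocosphaera(noise_cv = 0, seed = 1L)
  bad <- tr$n2fix_schedule
  bad$t_h[1] <- 5; bad$value[1] <- 3
  expect_error(
    synthetic_truth("x", tr$pe_etr, tr$pe_c, tr$resp_light, tr$resp_dark,
                    tr$gross_o2_schedule, bad, tr$fvfm, tr$chl,
                    tr$od_params),
    class = "dzd_config_error")
})

test_that("noise-free ethylene vials encode 4x the scheduled N2 rate", {
  tr <- truth_cyanothece(noise_cv = 0, seed = 3L)
  ds <- generate_diel_dataset(tr, diel_light_profile(130))
  ara <- ds$ethylene_vials
  expect_true(all(ara$t1_ppm >= ara$t0_ppm))   # non-decreasing ethylene
  eth <- ethylene_production_rate(ara$t0_ppm, ara$t1_ppm, ara$headspace_ml,
                                  ara$sample_ml, t_inc = ara$dt_h,
                                  chl = tr$chl / 1000)
  n2 <- n2_rate(eth)
  sched <- tr$n2fix_schedule
  rec <- n2[match(sched$t_h, ara$t_h)]
  expect_equal(rec, sched$value, tolerance = 1e-9)
})

test_that("normalized OD reproduces the configured diel folds", {
  tr <- truth_crocosphaera(noise_cv = 0, seed = 1L)
  ds <- generate_diel_dataset(tr, diel_light_profile(400))
  n <- normalize_od(ds$od_series$t_h, ds$od_series$od735)
  peak_i <- which.max(n$od_norm)
  expect_equal(n$od_norm[peak_i], 2.3, tolerance = 1e-3)
  expect_equal(n$t_h[peak_i], 9, tolerance = 0.3)
  expect_equal(n$od_norm[length(n$od_norm)], 1.4, tolerance = 0.01)
  # rises through the light phase after the anchor, falls through the dark
  expect_gt(min(diff(n$od_norm[n$t_h >= 1 & n$t_h <= 8])), 0)
  expect_lt(max(diff(n$od_norm[n$t_h >= 13])), 0)
})

test_that("noise-free generation supports 1e-6-level parameter recovery", {
  tr <- truth_crocosphaera(noise_cv = 0, seed = 1L)
  ds <- generate_diel_dataset(tr, diel_light_profile(400))
  ctx <- etr_context(chl = tr$chl)
  fit <- fit_etr_ladder(ds$frrf_tables[["5"]], ctx)
  expect_equal(fit$alpha, tr$pe_etr$alpha, tolerance = 1e-6)
  expect_equal(fit$Pmax, tr$pe_etr$Pmax, tolerance = 1e-6)
  expect_equal(fit$Ek, tr$pe_etr$Ek, tolerance = 1e-6)
  cfit <- fit_carbon_pe(ds$c14_counts, t_inc = 0.5, dic = 2050,
                        chl = tr$chl, discrimination = 1.05)
  expect_equal(cfit$Ek, 331, tolerance = 1e-6)
})
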