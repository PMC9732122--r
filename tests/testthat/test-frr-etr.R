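ctx100 <- etr_context(KA = 11800, chl = 100)

test_that("absorption-method ETR matches hand arithmetic", {
  y <- frrf_yields(F0 = 0.2, Fm = 0.5, Fp = 0.3, Fmp = 0.45, E = 100)
  # (0.5*0.2/0.3) * (0.15/0.45) * 100 * 11800/100 / 3600
  expect_equal(etr_from_yields(y, ctx100), 118 / 324, tolerance = 1e-12)
  expect_equal(etr_from_yields(y, ctx100), 0.3642, tolerance = 1e-4)
})

test_that("zero photochemistry and zero excitation give zero ETR", {
  y0 <- frrf_yields(F0 = 0.2, Fm = 0.5, Fp = 0.45, Fmp = 0.45, E = 300)
  expect_equal(etr_from_yields(y0, ctx100), 0)
  yE0 <- frrf_yields(F0 = 0.2, Fm = 0.5, Fp = 0.3, Fmp = 0.45, E = 0)
  expect_equal(etr_from_yields(yE0, ctx100), 0)
})

test_that("degenerate and unphysical yield sets are rejected", {
  expect_error(frrf_yields(0.5, 0.5, 0.3, 0.45, 100),
               class = "dzd_degenerate_yields")
  expect_error(frrf_yields(0.2, 0.5, 0.46, 0.45, 100),
               class = "dzd_invalid_measurement")
  bad <- data.frame(F0 = 0.2, Fm = 0.2, Fp = 0.3, Fmp = 0.45, E = 100)
  expect_error(etr_from_yields(bad, ctx100),
               class = "dzd_degenerate_yields")
})

test_that("ETR is linear in E and KA and inversely linear in chl", {
  base <- data.frame(F0 = 0.2, Fm = 0.5, Fp = 0.3, Fmp = 0.45, E = 100)
  r1 <- etr_from_yields(base, ctx100)
  for (s in c(0.5, 2, 7.3)) {
    scaled_E <- transform(base, E = E * s)
    expect_equal(etr_from_yields(scaled_E, ctx100), s * r1,
                 tolerance = 1e-12)
    expect_equal(etr_from_yields(base, etr_context(KA = 11800 * s, chl = 100)),
                 s * r1, tolerance = 1e-12)
    expect_equal(etr_from_yields(base, etr_context(KA = 11800, chl = 100 * s)),
                 r1 / s, tolerance = 1e-12)
  }
})

test_that("the time-factor flag flips the printed 1/3600 to x3600", {
  y <- frrf_yields(0.2, 0.5, 0.3, 0.45, 100)
  flipped <- etr_context(KA = 11800, chl = 100, invert_time_factor = TRUE)
  expect_equal(etr_from_yields(y, flipped),
               etr_from_yields(y, ctx100) * 3600^2, tolerance = 1e-12)
})

test_that("a ladder of inverse-generated yields refits the true curve", {
  truth <- pe_curve(alpha = 0.003, Pmax = 1.3, Eopt = 1200)
  ladder_E <- c(0, 30, 60, 120, 220, 350, 520, 740, 980, 1230, 1495)
  ctx <- etr_context(chl = 150)
  rows <- lapply(ladder_E[-1], function(E) {
    y <- yields_for_etr(predict(truth, E = E), E, fvfm = 0.45, chl = 150)
    data.frame(E = E, F0 = y$F0, Fm = y$Fm, Fp = y$Fp, Fmp = y$Fmp)
  })
  Fm <- 1 / (1 - 0.45)
  ladder <- rbind(data.frame(E = 0, F0 = 1, Fm = Fm, Fp = Fm, Fmp = Fm),
                  do.call(rbind, rows))
  fit <- fit_etr_ladder(ladder, ctx)
  expect_equal(fit$alpha, truth$alpha, tolerance = 1e-7)
  expect_equal(fit$Pmax, truth$Pmax, tolerance = 1e-7)
  expect_equal(fit$Ek, truth$Ek, tolerance = 1e-7)
})
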