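ladder <- c(0, 30, 60, 120, 220, 350, 520, 740, 980, 1230, 1495)

test_that("noise-free Eilers-Peeters data are recovered to 1e-6 relative", {
  a <- 1e-6; b <- 2e-3; c <- 0.5
  resp <- ifelse(ladder == 0, 0, ladder / (a * ladder^2 + b * ladder + c))
  fit <- fit_pe_curve(ladder, resp)
  expect_equal(fit$a, a, tolerance = 1e-6)
  expect_equal(fit$b, b, tolerance = 1e-6)
  expect_equal(fit$c, c, tolerance = 1e-6)
  expect_equal(fit$alpha, 1 / c, tolerance = 1e-6)
  expect_equal(fit$Pmax, 1 / (b + 2 * sqrt(a * c)), tolerance = 1e-6)
  expect_equal(fit$Eopt, sqrt(c / a), tolerance = 1e-6)
  expect_identical(fit$Ek, fit$Pmax / fit$alpha)
})

test_that("descriptor recovery holds across a parameter sweep", {
  cases <- expand.grid(alpha = c(7.16e-4, 2.86e-3, 9.9e-3),
                       Pmax = c(0.175, 1.26, 2.29),
                       Eopt = c(500, 900, 1300))
  # the design must include sub-saturating points: Ek below the lowest
  # non-zero ladder irradiance is outside the fitter's stated domain
  cases <- cases[cases$Pmax / cases$alpha >= min(ladder[ladder > 0]), ]
  for (i in seq_len(nrow(cases))) {
    truth <- pe_curve(cases$alpha[i], cases$Pmax[i], cases$Eopt[i])
    fit <- fit_pe_curve(ladder, predict(truth, E = ladder))
    expect_equal(fit$alpha, truth$alpha, tolerance = 1e-6)
    expect_equal(fit$Pmax, truth$Pmax, tolerance = 1e-6)
    expect_equal(fit$Ek, truth$Ek, tolerance = 1e-6)
  }
})

test_that("scaling all responses scales alpha and Pmax, not Ek", {
  truth <- pe_curve(0.003, 1.2, 1000)
  resp <- predict(truth, E = ladder)
  f1 <- fit_pe_curve(ladder, resp)
  f2 <- fit_pe_curve(ladder, 2 * resp)
  expect_equal(f2$alpha, 2 * f1$alpha, tolerance = 1e-6)
  expect_equal(f2$Pmax, 2 * f1$Pmax, tolerance = 1e-6)
  expect_equal(f2$Ek, f1$Ek, tolerance = 1e-6)
})

test_that("the fitted curve approaches alpha*E at low irradiance", {
  fit <- fit_pe_curve(ladder, predict(pe_curve(0.003, 1.2, 1000), E = ladder))
  # deviation from the initial-slope line shrinks linearly in E
  expect_equal(predict(fit, E = fit$Ek / 100), fit$alpha * fit$Ek / 100,
               tolerance = 5e-3)
  expect_equal(predict(fit, E = fit$Ek / 1000), fit$alpha * fit$Ek / 1000,
               tolerance = 5e-4)
})

test_that("refitting a fit's own curve is idempotent", {
  fit <- fit_pe_curve(ladder, predict(pe_curve(0.0029, 1.26, 1300),
                                      E = ladder))
  refit <- fit_pe_curve(ladder, predict(fit, E = ladder))
  expect_equal(refit$alpha, fit$alpha, tolerance = 1e-8)
  expect_equal(refit$Pmax, fit$Pmax, tolerance = 1e-8)
  expect_equal(refit$Eopt, fit$Eopt, tolerance = 1e-8)
})

test_that("fit is invariant to point ordering", {
  truth <- pe_curve(0.002, 0.8, 800)
  resp <- predict(truth, E = ladder)
  set.seed(7)
  perm <- sample(seq_along(ladder))
  f1 <- fit_pe_curve(ladder, resp)
  f2 <- fit_pe_curve(ladder[perm], resp[perm])
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-10)
  expect_equal(f2$Pmax, f1$Pmax, tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  expect_error(fit_pe_curve(c(0, 100, 200), c(0, 1, 2)),
               class = "dzd_insufficient_data")
  expect_error(fit_pe_curve(ladder, rep(0, length(ladder))),
               class = "dzd_insufficient_data")
  expect_error(fit_pe_curve(c(100, 100, 100, 100, 100), rep(1, 5)),
               class = "dzd_insufficient_data")
})

test_that("diel integration: dark phase of a light response is zero", {
  fit <- pe_curve(0.003, 1.2, 1000)
  prof <- diel_light_profile(400)
  expect_equal(integrate_diel(fit, prof, "dark"), 0)
})

test_that("diel integration of a linear response matches the sine closed form", {
  alpha <- 0.003
  lin <- pe_curve(alpha, 1e9, Inf)   # effectively P(E) = alpha * E
  for (E_max in c(130, 400)) {
    prof <- diel_light_profile(E_max)
    expect_equal(integrate_diel(lin, prof, "light"),
                 alpha * E_max * 24 / pi, tolerance = 1e-4)
  }
})

test_that("diel integration converges under step halving", {
  fit <- pe_curve(0.0029, 1.26, 1300)
  prof <- diel_light_profile(400)
  i1 <- integrate_diel(fit, prof, "light", dt = 0.1)
  i2 <- integrate_diel(fit, prof, "light", dt = 0.05)
  expect_equal(i1, i2, tolerance = 1e-4)
  expect_error(integrate_diel(fit, prof, "light", dt = 0.5),
               class = "dzd_config_error")
})

test_that("integration agrees with an independent quadrature", {
  skip_if_not_installed("pracma")
  fit <- pe_curve(0.0029, 1.26, 1300)
  prof <- diel_light_profile(400)
  t <- seq(0, 12, by = 0.05)
  oracle <- pracma::trapz(t, predict(fit, E = irradiance_at(
    pmin(t, 24 - 1e-9), prof)))
  expect_equal(integrate_diel(fit, prof, "light", dt = 0.05), oracle,
               tolerance = 1e-10)
})
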